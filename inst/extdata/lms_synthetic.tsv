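sex	age_months	L	M	S
male	0	-0.2	17	0.078
male	6	-0.4115	16.596	0.0794
male	12	-0.5982	16.286	0.0808
male	18	-0.7629	16.056	0.0822
male	24	-0.9082	15.894	0.0836
male	30	-1.0365	15.788	0.085
male	36	-1.1497	15.732	0.0864
male	42	-1.2496	15.716	0.0878
male	48	-1.3378	15.734	0.0892
male	54	-1.4156	15.783	0.0906
male	60	-1.4843	15.856	0.092
male	66	-1.5449	15.95	0.0934
male	72	-1.5984	16.061	0.0948
male	78	-1.6456	16.188	0.0962
male	84	-1.6872	16.328	0.0976
male	90	-1.724	16.478	0.099
male	96	-1.7564	16.638	0.1004
male	102	-1.785	16.805	0.1018
male	108	-1.8103	16.979	0.1032
male	114	-1.8326	17.159	0.1046
male	120	-1.8522	17.343	0.106
male	126	-1.8696	17.531	0.1074
male	132	-1.8849	17.722	0.1088
male	138	-1.8985	17.917	0.1102
male	144	-1.9104	18.113	0.1116
male	150	-1.9209	18.312	0.113
male	156	-1.9302	18.512	0.1144
male	162	-1.9384	18.714	0.1158
male	168	-1.9456	18.918	0.1172
male	174	-1.952	19.122	0.1186
male	180	-1.9577	19.327	0.12
male	186	-1.9626	19.533	0.1214
male	192	-1.967	19.739	0.1228
male	198	-1.9709	19.946	0.1242
male	204	-1.9743	20.154	0.1256
male	210	-1.9773	20.362	0.127
male	216	-1.98	20.57	0.1284
male	222	-1.9824	20.778	0.1298
male	228	-1.9844	20.987	0.1312
male	234	-1.9863	21.196	0.1326
male	240	-1.9879	21.405	0.134
female	0	-0.2	16.85	0.08
female	6	-0.4115	16.474	0.0814
female	12	-0.5982	16.189	0.0828
female	18	-0.7629	15.98	0.0842
female	24	-0.9082	15.837	0.0856
female	30	-1.0365	15.748	0.087
female	36	-1.1497	15.706	0.0884
female	42	-1.2496	15.704	0.0898
female	48	-1.3378	15.735	0.0912
female	54	-1.4156	15.794	0.0926
female	60	-1.4843	15.877	0.094
female	66	-1.5449	15.981	0.0954
female	72	-1.5984	16.101	0.0968
female	78	-1.6456	16.236	0.0982
female	84	-1.6872	16.383	0.0996
female	90	-1.724	16.541	0.101
female	96	-1.7564	16.708	0.1024
female	102	-1.785	16.881	0.1038
female	108	-1.8103	17.062	0.1052
female	114	-1.8326	17.247	0.1066
female	120	-1.8522	17.437	0.108
female	126	-1.8696	17.631	0.1094
female	132	-1.8849	17.828	0.1108
female	138	-1.8985	18.028	0.1122
female	144	-1.9104	18.231	0.1136
female	150	-1.9209	18.435	0.115
female	156	-1.9302	18.641	0.1164
female	162	-1.9384	18.848	0.1178
female	168	-1.9456	19.056	0.1192
female	174	-1.952	19.266	0.1206
female	180	-1.9577	19.476	0.122
female	186	-1.9626	19.687	0.1234
female	192	-1.967	19.899	0.1248
female	198	-1.9709	20.111	0.1262
female	204	-1.9743	20.323	0.1276
female	210	-1.9773	20.536	0.129
female	216	-1.98	20.75	0.1304
female	222	-1.9824	20.963	0.1318
female	228	-1.9844	21.177	0.1332
female	234	-1.9863	21.391	0.1346
female	240	-1.9879	21.605	0.136
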