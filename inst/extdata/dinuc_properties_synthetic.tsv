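property	AA	AC	AG	AU	CA	CC	CG	CU	GA	GC	GG	GU	UA	UC	UG	UU
A_content	1	0.5	0.5	0.5	0.5	0	0	0	0.5	0	0	0	0.5	0	0	0
C_content	0	0.5	0	0	0.5	1	0.5	0.5	0	0.5	0	0	0	0.5	0	0
G_content	0	0	0.5	0	0	0	0.5	0	0.5	0.5	1	0.5	0	0	0.5	0
U_content	0	0	0	0.5	0	0	0	0.5	0	0	0	0.5	0.5	0.5	0.5	1
GC_content	0	0.5	0.5	0	0.5	1	1	0.5	0.5	1	1	0.5	0	0.5	0.5	0
AU_content	1	0.5	0.5	1	0.5	0	0	0.5	0.5	0	0	0.5	1	0.5	0.5	1
purine_content	1	0.5	1	0.5	0.5	0	0.5	0	1	0.5	1	0.5	0.5	0	0.5	0
keto_content	0	0	0.5	0.5	0	0	0.5	0.5	0.5	0.5	1	1	0.5	0.5	1	1
synthetic_scale_01	0.2409	1.0517	-0.0577	-1.5193	-0.9114	0.5326	0.5442	1.8208	0.3477	1.7338	1.5945	-0.3237	1.9949	1.9544	1.3449	0.0634
synthetic_scale_02	1.1344	-0.9276	1.0595	0.5113	-0.1781	-0.9484	-0.3233	0.1546	-0.8033	0.8807	0.3534	1.8885	1.9534	-0.4653	-0.5327	0.1906
synthetic_scale_03	0.615	-0.9611	-1.677	0.9199	-1.2369	0.5888	-1.9738	-0.3645	1.2738	-1.6674	-0.9379	0.0395	-1.3216	1.0723	-0.4124	-1.6338
synthetic_scale_04	0.3702	-1.4353	-0.8055	1.1136	0.3181	-1.5675	1.7645	-0.2452	-1.4799	-1.3333	1.8772	0.2375	1.6376	1.4617	-1.4625	-0.1544
synthetic_scale_05	-1.8219	0.5621	1.2548	-1.1344	1.0159	-1.3263	-0.3261	1.7301	0.9136	-0.2757	0.5475	-0.853	-0.5526	-0.0128	0.9297	1.2541
synthetic_scale_06	1.3188	-0.2774	0.8311	-0.2134	1.2363	0.7183	-0.4327	1.9474	-1.3596	1.0774	-1.639	1.6471	-1.8628	-1.6029	0.7525	1.8035
synthetic_scale_07	-0.922	0.4882	-0.3581	-1.5612	-0.1688	0.7425	0.5853	1.7074	-0.0391	-0.7933	-1.8389	-1.6844	0.4905	1.8617	-0.609	1.545
synthetic_scale_08	0.7501	1.0116	-1.3768	1.33	1.0286	-1.0879	-0.8399	-0.8463	0.1467	1.6204	-0.577	1.7239	0.0897	0.001	1.3173	-0.4538
synthetic_scale_09	-0.1064	-0.6131	-0.3113	-1.8878	1.2061	-1.7284	1.3165	0.1348	-1.7239	-0.4821	-1.7761	0.5228	-1.5223	-1.6282	0.4537	-1.5813
synthetic_scale_10	-0.9661	0.0756	0.3904	-1.9779	0.8686	1.2227	-0.6758	0.8122	1.8552	-1.3013	-0.1628	-0.0067	0.7862	1.4246	0.9156	-0.6017
synthetic_scale_11	-1.6967	-1.7513	-0.0822	1.7027	-1.9406	1.9811	-1.5181	0.9046	-0.57	-1.1862	-1.1749	0.1638	0.1851	0.9454	0.3436	1.7766
synthetic_scale_12	1.8291	-0.4485	0.3647	-1.1601	-1.3132	1.9003	1.6055	1.1506	0.7412	1.4318	-0.499	1.3648	-1.1236	-1.0098	-0.0265	0.4218
synthetic_scale_13	1.609	-0.7335	-0.9305	1.0257	0.0904	1.3758	-0.3252	1.789	-1.8461	-0.3744	0.5415	-0.3669	-0.352	0.1187	-1.8502	1.2633
synthetic_scale_14	-0.936	0.6189	-1.5884	-0.5828	-0.3912	-1.4383	1.1396	-1.2062	-0.685	1.2069	-1.3747	-0.1307	-0.628	-1.3496	-1.232	1.9459
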