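metabolite	mean1	sd1	n1	mean2	sd2	n2	p	adjusted_p
Glucose	3.286	0.965	29	3.166	0.893	30	0.624	0.809
Pyruvate	0.279	0.093	29	0.306	0.085	30	0.259	0.567
Lactate	3.004	1.158	29	3.367	1.221	30	0.247	0.567
Citrate	0.263	0.076	29	0.303	0.097	30	0.087	0.329
Succinate	0.465	0.111	29	0.589	0.121	30	1.37e-04	0.005
Fumarate	0.159	0.06	29	0.146	0.05	30	0.377	0.66
Phenylalanine	0.198	0.053	29	0.226	0.048	30	0.038	0.171
Tyrosine	0.189	0.055	29	0.209	0.044	30	0.123	0.39
Aspartate	1.404	0.454	29	1.598	0.419	30	0.094	0.329
Glutamate	1.908	0.68	29	2.088	0.656	30	0.304	0.626
Glutamine	2.654	0.833	29	2.821	0.722	30	0.415	0.691
Glycine	1.488	0.564	29	1.428	0.589	30	0.690	0.833
Valine	0.447	0.099	29	0.509	0.121	30	0.036	0.171
Isoleucine	0.251	0.069	29	0.273	0.071	30	0.233	0.567
Leucine	0.464	0.13	29	0.507	0.113	30	0.182	0.49
Histidine	0.136	0.049	29	0.182	0.108	30	0.039	0.171
Alanine	1.128	0.268	29	1.291	0.298	30	0.031	0.171
Acetate	0.281	0.059	29	0.294	0.053	30	0.375	0.66
Formate	0.419	0.17	29	0.362	0.145	30	0.177	0.49
Inosine	0.318	0.151	29	0.332	0.192	30	0.760	0.847
Creatine	1.019	0.494	29	1.062	0.59	30	0.762	0.847
Hypoxanthine	0.672	0.283	29	0.683	0.233	30	0.873	0.926
Carnosine	0.019	0.012	29	0.019	0.012	30	0.959	0.97
Uridine	0.37	0.19	29	0.338	0.16	30	0.489	0.713
Taurine	4.089	1.612	29	4.351	2.288	30	0.614	0.809
3-hydroxybutytrate	0.308	0.111	29	0.366	0.304	30	0.338	0.657
Nicotinamide	0.126	0.066	29	0.113	0.071	30	0.475	0.713
NAD	0.016	0.007	29	0.024	0.011	30	0.001	0.015
AMP	0.009	0.005	29	0.009	0.008	30	0.774	0.847
ADP	0.016	0.01	29	0.017	0.011	30	0.657	0.822
Uracil	0.211	0.066	29	0.25	0.056	30	0.017	0.146
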