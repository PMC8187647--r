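metabolite	mean1	sd1	n1	mean2	sd2	n2	p	adjusted_p
Glucose	3.166	0.893	30	3.257	0.767	30	0.676	0.947
Pyruvate	0.306	0.085	30	0.279	0.09	30	0.251	0.828
Lactate	3.367	1.221	30	2.881	0.921	30	0.087	0.828
Citrate	0.303	0.097	30	0.277	0.085	30	0.282	0.828
Succinate	0.589	0.121	30	0.429	0.109	30	1.48e-06	5.18e-05
Fumarate	0.146	0.05	30	0.174	0.053	30	0.037	0.653
Phenylalanine	0.226	0.048	30	0.212	0.049	30	0.265	0.828
Tyrosine	0.209	0.044	30	0.208	0.061	30	0.910	0.992
Aspartate	1.598	0.419	30	1.502	0.484	30	0.413	0.828
Glutamate	2.088	0.656	30	1.874	0.684	30	0.221	0.828
Glutamine	2.821	0.722	30	2.659	0.731	30	0.391	0.828
Glycine	1.428	0.589	30	1.367	0.478	30	0.664	0.947
Valine	0.509	0.121	30	0.509	0.145	30	0.992	0.992
Isoleucine	0.273	0.071	30	0.295	0.107	30	0.370	0.828
Leucine	0.507	0.113	30	0.516	0.142	30	0.792	0.990
Histidine	0.182	0.108	30	0.168	0.098	30	0.594	0.945
Alanine	1.291	0.298	30	1.223	0.324	30	0.402	0.828
Acetate	0.294	0.053	30	0.307	0.072	30	0.426	0.828
Formate	0.362	0.145	30	0.415	0.214	30	0.264	0.828
Inosine	0.332	0.192	30	0.315	0.173	30	0.722	0.973
Creatine	1.062	0.59	30	1.023	0.503	30	0.784	0.990
Hypoxanthine	0.683	0.233	30	0.63	0.236	30	0.392	0.828
Carnosine	0.019	0.012	30	0.019	0.011	30	0.983	0.992
Uridine	0.338	0.16	30	0.342	0.17	30	0.932	0.992
Taurine	4.351	2.288	30	3.778	1.605	30	0.266	0.828
3-hydroxybutytrate	0.366	0.304	30	0.371	0.317	30	0.946	0.992
Nicotinamide	0.113	0.071	30	0.11	0.061	30	0.857	0.992
NAD	0.024	0.011	30	0.021	0.012	30	0.317	0.828
AMP	0.009	0.008	30	0.009	0.008	30	0.935	0.992
ADP	0.017	0.011	30	0.016	0.01	30	0.594	0.945
Uracil	0.25	0.056	30	0.235	0.068	30	0.355	0.828
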