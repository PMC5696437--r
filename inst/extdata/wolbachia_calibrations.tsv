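source	species_1	species_2	host_ks	host_ka	symbiont_ks	symbiont_ka	ratio	cladogenic
Drosophila_wRi_like	Drosophila_suzukii	Drosophila_subpulchrella	1.2e-1	6.8e-3	3e-5	4e-5	0.00025	FALSE
Nasonia_Raychoudhury2009	Nasonia_giraulti	Nasonia_longicornis	1.22e-2	5.4e-3	3.7e-3	2.2e-3	0.30	TRUE
Nomada_GerthBleidorn2017	Nomada_ferruginata	Nomada_leucophthalma	1.95e-2	2.6e-3	2.5e-3	9e-4	0.13	TRUE
Nomada_GerthBleidorn2017	Nomada_ferruginata	Nomada_flava	1.92e-2	2.7e-3	2.5e-3	9e-4	0.13	TRUE
Nomada_GerthBleidorn2017	Nomada_ferruginata	Nomada_panzeri	1.84e-2	3.1e-3	2.7e-3	1.1e-3	0.15	TRUE
Nomada_GerthBleidorn2017	Nomada_leucophthalma	Nomada_flava	6.8e-3	4e-4	1e-4	1e-4	0.015	TRUE
Nomada_GerthBleidorn2017	Nomada_leucophthalma	Nomada_panzeri	5.8e-3	8e-4	3e-4	2e-4	0.052	TRUE
Nomada_GerthBleidorn2017	Nomada_flava	Nomada_panzeri	5.5e-3	9e-4	3e-4	3e-4	0.055	TRUE
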