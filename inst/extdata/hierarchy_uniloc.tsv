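organelle	suborganelle	slot
nucleus	nucleolus	1
nucleus	nucleoplasm	2
nucleus	nuclear_envelope	3
nucleus	nuclear_matrix	4
nucleus	nuclear_speckle	5
nucleus	chromosome	6
nucleus	nuclear_pore_complex	7
cytoplasm	cytosol	1
cytoplasm	cytoskeleton	2
cytoplasm	centrosome	3
cytoplasm	cytoplasmic_granule	4
cytoplasm	p_body	5
cytoplasm	stress_granule	6
cytoplasm	myofibril	7
cytoplasm	perinuclear_region	8
extracellular	secreted	1
extracellular	extracellular_matrix	2
extracellular	cell_surface	3
mitochondrion	matrix	1
mitochondrion	inner_membrane	2
mitochondrion	outer_membrane	3
mitochondrion	intermembrane_space	4
cell_membrane	sarcolemma	1
cell_membrane	apical_membrane	2
cell_membrane	basolateral_membrane	3
cell_membrane	lateral_membrane	4
endoplasmic_reticulum	er_lumen	1
endoplasmic_reticulum	er_membrane	2
endoplasmic_reticulum	rough_er	3
endoplasmic_reticulum	smooth_er	4
endoplasmic_reticulum	sarcoplasmic_reticulum	5
plastid	stroma	1
plastid	thylakoid_lumen	2
plastid	thylakoid_membrane	3
plastid	plastid_envelope	4
plastid	amyloplast	5
golgi_apparatus	cis_golgi_network	1
golgi_apparatus	trans_golgi_network	2
golgi_apparatus	golgi_membrane	3
golgi_apparatus	golgi_stack_membrane	4
lysosome_vacuole	lysosome_lumen	1
lysosome_vacuole	lysosome_membrane	2
peroxisome	peroxisome_matrix	1
peroxisome	peroxisome_membrane	2
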