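species	level1	level2
Aloe_demoensis	Medicines	Medicines
Aloe_demoensis	Food	
Aloe_exempli	Medicines	Medicines
Aloe_ficta	Materials	
Aloe_simulata	Medicines	Medicines
Aloe_synthetica	Social_uses	
Aloe_arenaria_syn	Medicines	Medicines
Aloidendron_fictum	Materials	
Kumara_simulata	Environmental_uses	
Aristaloe_ficta	Medicines	Medicines
Aloe_montana_syn	Food	
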