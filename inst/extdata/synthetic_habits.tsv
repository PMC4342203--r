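species	habit
Aloe_demoensis	succulent_shrub
Aloe_exempli	succulent_shrub
Aloe_ficta	succulent_shrub
Aloe_simulata	succulent_shrub
Aloe_synthetica	succulent_shrub
Aloe_arenaria_syn	succulent_shrub
Aloe_montana_syn	succulent_shrub
Aloe_parva_syn	succulent_shrub
Aloidendron_fictum	branching_tree
Aloiampelos_ficta	scrambling_shrub
Kumara_simulata	branching_tree
Aristaloe_ficta	succulent_shrub
Gonialoe_ficta	succulent_shrub
Aloe_litoralis_syn	barely_succulent_shrub
Aloe_collina_syn	barely_succulent_shrub
Aloe_vallis_syn	barely_succulent_shrub
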