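((((((((Aloe_arenaria_syn:0.382694021515,Aristaloe_ficta:0.382694021515):0.165493126691,(Kumara_simulata:0.00685832517406,Aloe_vallis_syn:0.00685832517406):0.541328823032):0.654840623306,Aloe_parva_syn:1.20302777151):0.250103768886,((Aloidendron_fictum:0.0963126731841,Aloe_collina_syn:0.0963126731841):0.573100564871,Aloe_simulata:0.669413238055):0.783718302342):0.0229965568914,(Aloe_synthetica:0.357407373758,Gonialoe_ficta:0.357407373758):1.11872072353):0.0983191584047,((Aloe_demoensis:0.217382876949,Aloe_litoralis_syn:0.217382876949):0.420910731586,Aloiampelos_ficta:0.638293608534):0.936153647159):0.170708616426,Aloe_ficta:1.74515587212):0.429141273235,(Aloe_exempli:1.26112989635,Aloe_montana_syn:1.26112989635):0.913167249007);
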