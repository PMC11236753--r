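parameter,symbol,value,unit
Axon diameter,d,2-16,um
Internodal distance,delta_x,155-1500,um
Node length,L,2.5,um
Specific axon resistance,rho_i,0.7,ohm_m
Membrane conductance per unit area,g_m,30.4,mS_per_cm2
Membrane capacitance per unit area,c_m,2,uF_per_cm2
Resting potential,V_r,-70,mV
Threshold potential,V_th,-55,mV
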