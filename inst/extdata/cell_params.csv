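cell_type,g_na,e_na,g_k,e_k,g_l,e_l,g_d,g_h,e_h,g_p,iapp_baseline,noise_k,cm
VIP,112.5,50,225,-90,0.25,-70,3,0,0,0,4,5,1
SOM,52,55,11,-90,0.62,-65,0,1.45,-20,0.5,0.1,4,1
PV,100,50,80,-100,0.1,-67,0,0,0,0,0,4,1
E,100,50,80,-100,0.1,-67,0,0,0,0,0.35,4,1
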