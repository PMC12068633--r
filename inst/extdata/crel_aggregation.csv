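system,t_ns,V_nm3,Rg_nm,Rg_in_water_nm
SC,800,856.235,6.023,5.753
SC,900,855.855,6.017,5.745
SC,1000,856.155,6.023,5.735
HC,800,860.644,6.03,5.81
HC,900,860.61,6.035,5.8
HC,1000,860.24,6.039,5.785
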