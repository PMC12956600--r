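#id=demo01
#group=children
#sex=F
#age_y=9.5
#body_mass_kg=32.3
#height_cm=139
#warmup_start_s=0
#ramp_start_s=1
#termination_s=4
#ramp_start_W=20
#ramp_rate_W_per_min=15
t_s,vo2_ml_min,vco2_ml_min,ve_l_min,hr_bpm,peto2_mmhg,petco2_mmhg,power_w
0,500,425,12.5,95,90,40,20
2.1,520,444,13,96,90,40,20
4,540,460,13.4,,90,40,20
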