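#id=demo02
#group=MTA
#sex=M
#age_y=25
#body_mass_kg=75
#height_cm=180
#warmup_start_s=0
#ramp_start_s=1
#termination_s=4
t_s,vo2_ml_min,vco2_ml_min,ve_ml_min,hr_bpm,peto2_mmhg,petco2_mmhg,power_w
0,800,700,21500,80,90,40,50
2.1,810,710,21800,81,90,40,50
4,820,720,22100,82,90,40,50
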