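study_label,n_f,n_m,mean_f,mean_m,sd_f,sd_m,presentations,stimulus_group
synthA_clicks,34,36,11.8,11.6,3.1,3.3,512,air-conducted
synthB_clicks,11,12,12.3,11.9,2.8,3.0,768,air-conducted
synthC_tb500,14,15,11.2,11.5,3.4,2.9,150,air-conducted
synthD_tb500,40,40,11.6,11.9,3.0,3.1,,air-conducted
synthE_clicks,24,11,12.1,11.4,3.6,3.2,256,air-conducted
synthF_tb500,22,22,11.0,11.7,2.7,2.9,400,air-conducted
synthG_tb1000,40,38,10.9,12.0,2.9,3.0,800,air-conducted
synthH_mixed,28,33,11.5,11.8,3.2,3.4,256,body-conducted
synthI_tb750,31,11,11.9,11.6,3.5,3.1,,body-conducted
synthJ_bc500,24,24,10.1,12.3,2.8,2.6,3044,body-conducted
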