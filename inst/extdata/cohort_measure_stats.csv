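"measure_id","nf_mean","nf_sd","f_mean","f_sd","source"
"sit_eo_firm_es_ap",92,3.5,92,3.5,"null"
"sit_eo_firm_rms_acc_ap",0.008,0.003,0.008,0.003,"null"
"sit_eo_firm_rms_gyro_ap",1.2,0.3,1.2,0.3,"null"
"sit_eo_firm_jerk_acc_ap",0.043,0.012,0.039,0.009,"printed"
"sit_eo_firm_jerk_gyro_ap",30,10,30,10,"null"
"sit_eo_firm_medfreq_acc_ap",0.7,0.25,0.7,0.25,"null"
"sit_eo_firm_medfreq_gyro_ap",0.8,0.25,0.8,0.25,"null"
"sit_eo_firm_cenfreq_acc_ap",1,0.3,1,0.3,"null"
"sit_eo_firm_cenfreq_gyro_ap",1.1,0.3,1.1,0.3,"null"
"sit_eo_firm_power_acc_ap",1e-04,4e-05,1e-04,4e-05,"null"
"sit_eo_firm_power_gyro_ap",1.4,0.5,1.4,0.5,"null"
"sit_eo_firm_rms_tilt_ap",0.3,0.1,0.3,0.1,"null"
"sit_eo_firm_sway_range_ap",1.5,0.5,1.5,0.5,"null"
"sit_eo_firm_es_ml",92,3.5,92,3.5,"null"
"sit_eo_firm_rms_acc_ml",0.008,0.003,0.008,0.003,"null"
"sit_eo_firm_rms_gyro_ml",1.2,0.3,1.2,0.3,"null"
"sit_eo_firm_jerk_acc_ml",0.045,0.013,0.045,0.013,"null"
"sit_eo_firm_jerk_gyro_ml",30,10,30,10,"null"
"sit_eo_firm_medfreq_acc_ml",0.7,0.25,0.7,0.25,"null"
"sit_eo_firm_medfreq_gyro_ml",0.8,0.25,0.8,0.25,"null"
"sit_eo_firm_cenfreq_acc_ml",1,0.3,1,0.3,"null"
"sit_eo_firm_cenfreq_gyro_ml",1.1,0.3,1.1,0.3,"null"
"sit_eo_firm_power_acc_ml",1e-04,4e-05,1e-04,4e-05,"null"
"sit_eo_firm_power_gyro_ml",1.4,0.5,1.4,0.5,"null"
"sit_eo_firm_rms_tilt_ml",0.3,0.1,0.3,0.1,"null"
"sit_eo_firm_sway_range_ml",1.5,0.5,1.5,0.5,"null"
"sit_ec_firm_es_ap",92,3.5,92,3.5,"null"
"sit_ec_firm_rms_acc_ap",0.008,0.003,0.008,0.003,"null"
"sit_ec_firm_rms_gyro_ap",1.2,0.3,1.2,0.3,"null"
"sit_ec_firm_jerk_acc_ap",0.049,0.016,0.044,0.012,"printed"
"sit_ec_firm_jerk_gyro_ap",30,10,30,10,"null"
"sit_ec_firm_medfreq_acc_ap",0.7,0.25,0.7,0.25,"null"
"sit_ec_firm_medfreq_gyro_ap",0.8,0.25,0.8,0.25,"null"
"sit_ec_firm_cenfreq_acc_ap",1,0.3,1,0.3,"null"
"sit_ec_firm_cenfreq_gyro_ap",1.1,0.3,1.1,0.3,"null"
"sit_ec_firm_power_acc_ap",1e-04,4e-05,1e-04,4e-05,"null"
"sit_ec_firm_power_gyro_ap",1.4,0.5,1.4,0.5,"null"
"sit_ec_firm_rms_tilt_ap",0.3,0.1,0.3,0.1,"null"
"sit_ec_firm_sway_range_ap",1.5,0.5,1.5,0.5,"null"
"sit_ec_firm_es_ml",92,3.5,92,3.5,"null"
"sit_ec_firm_rms_acc_ml",0.008,0.003,0.008,0.003,"null"
"sit_ec_firm_rms_gyro_ml",1.2,0.3,1.2,0.3,"null"
"sit_ec_firm_jerk_acc_ml",0.045,0.013,0.045,0.013,"null"
"sit_ec_firm_jerk_gyro_ml",30,10,30,10,"null"
"sit_ec_firm_medfreq_acc_ml",0.7,0.25,0.7,0.25,"null"
"sit_ec_firm_medfreq_gyro_ml",0.8,0.25,0.8,0.25,"null"
"sit_ec_firm_cenfreq_acc_ml",1,0.3,1,0.3,"null"
"sit_ec_firm_cenfreq_gyro_ml",1.1,0.3,1.1,0.3,"null"
"sit_ec_firm_power_acc_ml",1e-04,4e-05,1e-04,4e-05,"null"
"sit_ec_firm_power_gyro_ml",1.4,0.5,1.4,0.5,"null"
"sit_ec_firm_rms_tilt_ml",0.3,0.1,0.3,0.1,"null"
"sit_ec_firm_sway_range_ml",1.5,0.5,1.5,0.5,"null"
"sit_eo_foam_es_ap",85,4.4,83,5.2,"synthetic"
"sit_eo_foam_rms_acc_ap",0.01,0.01,0.02,0.01,"printed"
"sit_eo_foam_rms_gyro_ap",1.38,0.22,1.47,0.29,"printed"
"sit_eo_foam_jerk_acc_ap",1.78,0.49,2.04,0.61,"printed"
"sit_eo_foam_jerk_gyro_ap",30,10,30,10,"null"
"sit_eo_foam_medfreq_acc_ap",0.7,0.25,0.7,0.25,"null"
"sit_eo_foam_medfreq_gyro_ap",0.8,0.25,0.8,0.25,"null"
"sit_eo_foam_cenfreq_acc_ap",1,0.3,1,0.3,"null"
"sit_eo_foam_cenfreq_gyro_ap",1.1,0.3,1.1,0.3,"null"
"sit_eo_foam_power_acc_ap",1e-04,4e-05,1e-04,4e-05,"null"
"sit_eo_foam_power_gyro_ap",1.4,0.5,1.4,0.5,"null"
"sit_eo_foam_rms_tilt_ap",0.3,0.1,0.3,0.1,"null"
"sit_eo_foam_sway_range_ap",1.5,0.5,1.5,0.5,"null"
"sit_eo_foam_es_ml",84.04,4.34,82.03,5.2,"printed"
"sit_eo_foam_rms_acc_ml",0.006,0.001,0.007,0.002,"printed"
"sit_eo_foam_rms_gyro_ml",1.2,0.3,1.2,0.3,"null"
"sit_eo_foam_jerk_acc_ml",1.81,0.51,2.01,0.61,"printed"
"sit_eo_foam_jerk_gyro_ml",30,10,30,10,"null"
"sit_eo_foam_medfreq_acc_ml",0.7,0.25,0.7,0.25,"null"
"sit_eo_foam_medfreq_gyro_ml",0.8,0.25,0.8,0.25,"null"
"sit_eo_foam_cenfreq_acc_ml",1,0.3,1,0.3,"null"
"sit_eo_foam_cenfreq_gyro_ml",1.1,0.3,1.1,0.3,"null"
"sit_eo_foam_power_acc_ml",1e-04,4e-05,1e-04,4e-05,"null"
"sit_eo_foam_power_gyro_ml",1.4,0.5,1.4,0.5,"null"
"sit_eo_foam_rms_tilt_ml",0.3,0.1,0.3,0.1,"null"
"sit_eo_foam_sway_range_ml",1.5,0.5,1.5,0.5,"null"
"sit_ec_foam_es_ap",84,4.5,84,4.5,"null"
"sit_ec_foam_rms_acc_ap",0.012,0.004,0.012,0.004,"null"
"sit_ec_foam_rms_gyro_ap",1.2,0.3,1.2,0.3,"null"
"sit_ec_foam_jerk_acc_ap",2.78,1.24,3.23,2.04,"printed"
"sit_ec_foam_jerk_gyro_ap",30,10,30,10,"null"
"sit_ec_foam_medfreq_acc_ap",0.7,0.25,0.7,0.25,"null"
"sit_ec_foam_medfreq_gyro_ap",0.8,0.25,0.8,0.25,"null"
"sit_ec_foam_cenfreq_acc_ap",1,0.3,1,0.3,"null"
"sit_ec_foam_cenfreq_gyro_ap",1.1,0.3,1.1,0.3,"null"
"sit_ec_foam_power_acc_ap",1e-04,4e-05,1e-04,4e-05,"null"
"sit_ec_foam_power_gyro_ap",1.4,0.5,1.4,0.5,"null"
"sit_ec_foam_rms_tilt_ap",0.3,0.1,0.3,0.1,"null"
"sit_ec_foam_sway_range_ap",1.5,0.5,1.5,0.5,"null"
"sit_ec_foam_es_ml",84,4.5,84,4.5,"null"
"sit_ec_foam_rms_acc_ml",0.012,0.004,0.012,0.004,"null"
"sit_ec_foam_rms_gyro_ml",1.2,0.3,1.2,0.3,"null"
"sit_ec_foam_jerk_acc_ml",2,0.6,2,0.6,"null"
"sit_ec_foam_jerk_gyro_ml",30,10,30,10,"null"
"sit_ec_foam_medfreq_acc_ml",0.7,0.25,0.7,0.25,"null"
"sit_ec_foam_medfreq_gyro_ml",0.8,0.25,0.8,0.25,"null"
"sit_ec_foam_cenfreq_acc_ml",1,0.3,1,0.3,"null"
"sit_ec_foam_cenfreq_gyro_ml",1.1,0.3,1.1,0.3,"null"
"sit_ec_foam_power_acc_ml",1e-04,4e-05,1e-04,4e-05,"null"
"sit_ec_foam_power_gyro_ml",1.4,0.5,1.4,0.5,"null"
"sit_ec_foam_rms_tilt_ml",0.3,0.1,0.3,0.1,"null"
"sit_ec_foam_sway_range_ml",1.5,0.5,1.5,0.5,"null"
"sit_som_ap",98,2,98,2,"null"
"sit_som_ml",98,2,98,2,"null"
"sit_vis_ap",90,4.8,88,5.5,"synthetic"
"sit_vis_ml",89.1,4.3,87,5.2,"printed"
"sit_vest_ap",80,8,80,8,"null"
"sit_vest_ml",80,8,80,8,"null"
"los_reach_distance",0.25,0.05,0.25,0.05,"null"
"los_rms_gyro_ap",12,4,12,4,"null"
"los_jerk_gyro_ap",26,3,26,3,"null"
"los_rms_gyro_ml",13,3.6,11.6,3.4,"synthetic"
"los_jerk_gyro_ml",26.24,3.15,24.96,2.79,"printed"
"los_rms_gyro_v",12,4,12,4,"null"
"los_jerk_gyro_v",26,3,26,3,"null"
"sts5_duration_sit_stand",0.97,0.19,1.17,0.39,"printed"
"sts5_mean_av_sit_stand",95,22,82,24,"synthetic"
"sts5_max_av_sit_stand",150,35,150,35,"null"
"sts5_jerk_sit_stand",1450,520,1180,600,"synthetic"
"sts5_duration_stand_sit",1.08,0.26,1.32,0.55,"printed"
"sts5_mean_av_stand_sit",90,22,80,24,"synthetic"
"sts5_max_av_stand_sit",150,35,150,35,"null"
"sts5_jerk_stand_sit",1507.23,519.93,1318.21,650.68,"printed"
"sts5_duration_sit_stand_sit",2.05,0.43,2.44,0.78,"printed"
"sts5_mean_av_sit_stand_sit",92,20,81,23,"synthetic"
"sts5_max_av_sit_stand_sit",158,34,142,38,"synthetic"
"sts5_jerk_sit_stand_sit",1592.92,553.47,1341.82,651.17,"printed"
"tug_gait_velocity",0.77,0.11,0.68,0.12,"printed"
"tug_step_time",1.04,0.08,1.08,0.13,"printed"
"tug_step_time_alt",0.53,0.05,0.53,0.05,"null"
"tug_step_time_sd",0.045,0.018,0.055,0.025,"synthetic"
"tug_step_length",0.39,0.04,0.36,0.04,"printed"
"tug_n_steps",16,2,16,2,"null"
"tug_walk_time",8,1.3,9,1.8,"synthetic"
"tug_total_time",11.5,2,11.5,2,"null"
"tug_rms_acc_ap",0.008,0.003,0.008,0.003,"null"
"tug_rms_gyro_ap",25,6,22.6,6,"synthetic"
"tug_jerk_acc_ap",1.5,0.5,1.5,0.5,"null"
"tug_rms_acc_ml",0.008,0.003,0.008,0.003,"null"
"tug_rms_gyro_ml",18,5,15.8,5,"synthetic"
"tug_jerk_acc_ml",1.5,0.5,1.5,0.5,"null"
"tug_rms_acc_v",0.008,0.003,0.008,0.003,"null"
"tug_rms_gyro_v",18,4,15.5,4.5,"synthetic"
"tug_jerk_acc_v",1.5,0.5,1.5,0.5,"null"
"tug_turn_time",2.11,0.43,2.43,0.61,"printed"
"tug_turn_rms_av",84.64,10.33,76.63,13.83,"printed"
"tug_turn_max_av",113.78,10.89,104.93,16.31,"printed"
"tug_turn_mean_av",75,12,75,12,"null"
"mf_knee_flexion_rom",131.73,13.38,124.95,12.99,"printed"
"mf_knee_extension_rom",4.29,1.55,3.69,1.82,"printed"
"crt_information_processing_speed",7.09,1.28,5.82,1.27,"printed"
"crt_simple_reaction_time",0.44,0.1,0.44,0.1,"null"
"fes_score",9.73,2.98,14.96,4.92,"printed"
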