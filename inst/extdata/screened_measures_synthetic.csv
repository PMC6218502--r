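"measure_id"
"fes_score"
"crt_information_processing_speed"
"tug_step_length"
"tug_gait_velocity"
"tug_step_time"
"tug_walk_time"
"tug_step_time_sd"
"tug_rms_gyro_ap"
"tug_rms_gyro_ml"
"tug_rms_gyro_v"
"tug_turn_time"
"tug_turn_rms_av"
"tug_turn_max_av"
"sts5_duration_sit_stand"
"sts5_duration_stand_sit"
"sts5_duration_sit_stand_sit"
"sts5_mean_av_sit_stand"
"sts5_mean_av_stand_sit"
"sts5_mean_av_sit_stand_sit"
"sts5_jerk_sit_stand"
"sts5_jerk_stand_sit"
"sts5_jerk_sit_stand_sit"
"sts5_max_av_sit_stand_sit"
"mf_knee_flexion_rom"
"mf_knee_extension_rom"
"sit_vis_ml"
"sit_vis_ap"
"sit_eo_foam_es_ml"
"sit_eo_foam_es_ap"
"sit_eo_foam_rms_gyro_ap"
"sit_eo_foam_rms_acc_ap"
"sit_eo_foam_rms_acc_ml"
"sit_eo_foam_jerk_acc_ap"
"sit_eo_foam_jerk_acc_ml"
"sit_eo_firm_jerk_acc_ap"
"sit_ec_firm_jerk_acc_ap"
"los_jerk_gyro_ml"
"los_rms_gyro_ml"
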