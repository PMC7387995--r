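variable,level,control,case
gender,boy,572,311
gender,girl,323,573
school,primary,359,239
school,junior,374,458
school,senior,162,187
shoulder_height_diff,normal,779,410
shoulder_height_diff,left,73,252
shoulder_height_diff,right,43,222
scapular_tilt,normal,764,268
scapular_tilt,left,85,349
scapular_tilt,right,46,267
lumbar_concave,normal,814,450
lumbar_concave,left,31,181
lumbar_concave,right,50,253
pelvic_tilt,normal,860,694
pelvic_tilt,left,23,68
pelvic_tilt,right,12,122
flat_back,normal,893,875
flat_back,abnormal,2,9
thoracic_kyphosis,normal,886,851
thoracic_kyphosis,abnormal,9,33
lumbar_kyphosis,normal,891,882
lumbar_kyphosis,abnormal,4,2
atr_thoracic,normal_0_5,853,565
atr_thoracic,left_gt5,18,90
atr_thoracic,right_gt5,24,229
atr_thoracolumbar,normal_0_5,872,796
atr_thoracolumbar,left_gt5,9,42
atr_thoracolumbar,right_gt5,14,46
atr_lumbar,normal_0_5,816,511
atr_lumbar,left_gt5,61,277
atr_lumbar,right_gt5,18,96
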