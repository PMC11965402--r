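posture,exercise,trajectory_condition,body_part,predicted_deg,actual_deg,error_deg
Sitting on the chair starting position,ready,none,lower_limb,177.32,180,-2.68
Sitting on the chair starting position,ready,none,lower_limb,135.95,123,4.95
Performing left leg exercise,hip_flexion,greater than 160 and smaller than 15,right_leg_normal,151.52,148,3.52
Performing right leg exercise,hip_flexion,greater than 160 and smaller than 15,left_leg_normal,141.35,142,-0.65
Performing left leg exercise,hip_flexion,greater than 160 and smaller than 15,left_leg_complete,12.49,12.84,-0.34
Performing right leg exercise,hip_flexion,greater than 160 and smaller than 15,right_leg_complete,3.51,6.1,-2.59
Performing left leg exercise,hip_external_rotation,greater than 150 and smaller than 30,left_leg_complete,45,46,-1
Performing left leg exercise,hip_external_rotation,greater than 150 and smaller than 30,right_leg_normal,90,93,-3
Performing left leg exercise,knee_extension,greater than 160 and smaller than 95,left_leg_complete,85,88,-3
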