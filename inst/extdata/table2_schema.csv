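joint,kind,categories,sensor_ids
He,classification,up;down;left;right;front,head
S(L),classification,up;down;left;right;front,shoulder_L;upper_arm_L
S(R),classification,up;down;left;right;front,shoulder_R;upper_arm_R
E(L),regression,,upper_arm_L;lower_arm_L
E(R),regression,,upper_arm_R;lower_arm_R
Wr(L),regression,,lower_arm_L;hand_L
Wr(R),regression,,lower_arm_R;hand_R
Ha(L),classification,normal;grasp;pointing,hand_L;finger1_L;finger2_L;finger3_L;finger4_L;finger5_L;finger6_L;finger7_L
Ha(R),classification,normal;grasp;pointing,hand_R;finger1_R;finger2_R;finger3_R;finger4_R;finger5_R;finger6_R;finger7_R
Wa,classification,straight;bend;twist-L;twist-R,spine;hip
HJ(L),regression,,hip;upper_leg_L
HJ(R),regression,,hip;upper_leg_R
K(L),regression,,upper_leg_L;lower_leg_L;foot_L
K(R),regression,,upper_leg_R;lower_leg_R;foot_R
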