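variable,label,mean_1,mean_2,mean_3,sem,cv,icc
AccMov_LA,Accuracy of movement: left arm,5.23,5.14,5.30,0.47,8.99,0.74
AccMov_RA,Accuracy of movement: right arm,5.07,4.74,4.89,1.03,20.90,0.40
Veloc_LA,Left arm speed,7.31,7.15,7.25,0.40,5.60,0.51
Veloc_RA,Right arm speed,7.23,7.09,7.10,0.57,8.02,0.67
VarMov_LA,Variation of movement: left arm,1.07,1.14,1.17,0.25,22.13,0.88
VarMov_RA,Variation of movement: right arm,0.62,0.64,0.59,0.14,22.46,0.89
InvMov_LA,Involuntary movement: left arm,7.26,7.09,7.37,0.33,4.62,0.66
InvMov_RA,Involuntary movement: right arm,8.47,8.10,8.05,1.53,19.84,0.38
VarMov_LL,Variation of movement: left leg,8.18,7.51,7.62,1.13,14.56,0.48
VarMov_RL,Variation of movement: right leg,8.86,8.36,8.13,1.58,18.67,0.68
MonSt_Bal_LL,Balance: left leg,47.59,47.45,47.10,3.12,6.48,0.90
MonSt_Bal_RL,Balance: right leg,37.99,37.69,36.50,6.61,17.60,0.80
AmpStep_LL,Side step width: left leg,27.65,26.80,28.33,3.95,14.32,0.92
AmpStep_RL,Side step width: right leg,27.47,26.87,28.04,3.09,11.27,0.95
Var_Mov_axial,Variation of axial movement,2.30,2.07,2.12,1.01,44.66,0.47
Bal_axial,Axial balance,2.99,3.01,2.95,0.29,9.71,0.60
Stab_axial,Axial stability,3.20,3.36,3.18,0.68,20.85,0.39
Posture_CST,Posture: sitting down and standing up,3.06,3.63,3.63,0.07,1.93,0.84
Asymmetry_UL,Upper limb asymmetry,8.39,7.83,7.44,2.37,30.05,0.79
Asymmetry_LL,Lower limb asymmetry,19.90,20.56,20.78,3.81,18.03,0.35
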