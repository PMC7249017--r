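dataset,condition,classifier,recall,specificity,accuracy,precision,f_measure
PS,FEET,RF,0.900,0.950,0.925,0.947,0.923
PS,FEET,SVM_L,0.900,0.900,0.900,0.900,0.900
PS,FEET,SVM_G,0.850,1.000,0.925,1.000,0.919
PS,FEET,SVM_P,0.900,0.900,0.900,0.900,0.900
PS,FEET,NB,0.850,1.000,0.925,1.000,0.930
PS,HANDS,RF,0.975,0.975,0.975,0.975,0.975
PS,HANDS,SVM_L,0.975,1.000,0.988,0.988,0.987
PS,HANDS,SVM_G,0.975,1.000,0.988,1.000,0.987
PS,HANDS,SVM_P,0.975,0.975,0.975,0.975,0.975
PS,HANDS,NB,0.975,0.900,0.938,0.907,0.939
PS,FULL,RF,0.975,1.000,0.975,1.000,0.976
PS,FULL,SVM_L,0.975,1.000,0.988,1.000,0.987
PS,FULL,SVM_G,0.975,1.000,0.988,1.000,0.987
PS,FULL,SVM_P,0.950,1.000,0.975,1.000,0.976
PS,FULL,NB,0.900,0.950,0.925,0.947,0.926
PC,FEET,RF,0.925,0.950,0.938,0.949,0.937
PC,FEET,SVM_L,0.925,0.900,0.913,0.902,0.914
PC,FEET,SVM_G,0.950,0.925,0.938,0.927,0.938
PC,FEET,SVM_P,0.900,0.975,0.938,0.973,0.939
PC,FEET,NB,0.850,1.000,0.925,1.000,0.930
PC,HANDS,RF,0.975,1.000,0.988,1.000,0.987
PC,HANDS,SVM_L,0.975,0.975,0.975,0.975,0.975
PC,HANDS,SVM_G,1.000,0.975,0.988,0.976,0.988
PC,HANDS,SVM_P,0.950,0.925,0.938,0.927,0.938
PC,HANDS,NB,0.950,0.900,0.925,0.905,0.926
PC,FULL,RF,0.950,1.000,0.975,1.000,0.976
PC,FULL,SVM_L,0.925,1.000,0.963,1.000,0.961
PC,FULL,SVM_G,1.000,1.000,1.000,1.000,1.000
PC,FULL,SVM_P,0.950,1.000,0.975,1.000,0.976
PC,FULL,NB,0.925,0.925,0.925,0.925,0.925
PS_B,FEET,RF,0.925,0.950,0.938,0.949,0.937
PS_B,FEET,SVM_L,0.900,1.000,0.950,1.000,0.947
PS_B,FEET,SVM_G,0.900,1.000,0.950,1.000,0.947
PS_B,FEET,SVM_P,0.975,0.925,0.950,0.929,0.951
PS_B,FEET,NB,0.850,1.000,0.925,1.000,0.930
PS_B,HANDS,RF,0.850,0.975,0.913,0.971,0.907
PS_B,HANDS,SVM_L,0.950,0.975,0.963,0.963,0.962
PS_B,HANDS,SVM_G,0.950,0.975,0.963,0.974,0.962
PS_B,HANDS,SVM_P,0.925,1.000,0.963,1.000,0.964
PS_B,HANDS,NB,0.950,0.975,0.963,0.974,0.963
PS_B,FULL,RF,0.950,0.975,0.988,0.974,0.988
PS_B,FULL,SVM_L,1.000,1.000,1.000,1.000,1.000
PS_B,FULL,SVM_G,0.975,1.000,0.988,1.000,0.987
PS_B,FULL,SVM_P,0.975,1.000,0.988,0.974,0.988
PS_B,FULL,NB,0.950,0.975,0.963,0.974,0.963
PC_B,FEET,RF,0.900,0.950,0.925,0.947,0.923
PC_B,FEET,SVM_L,0.950,0.950,0.950,0.950,0.950
PC_B,FEET,SVM_G,0.900,0.950,0.925,0.947,0.923
PC_B,FEET,SVM_P,0.950,0.975,0.963,0.974,0.963
PC_B,FEET,NB,0.850,1.000,0.925,1.000,0.930
PC_B,HANDS,RF,0.925,1.000,0.963,1.000,0.961
PC_B,HANDS,SVM_L,0.900,0.950,0.925,0.926,0.923
PC_B,HANDS,SVM_G,0.925,0.975,0.950,0.974,0.949
PC_B,HANDS,SVM_P,0.900,1.000,0.950,1.000,0.952
PC_B,HANDS,NB,0.975,0.975,0.975,0.975,0.975
PC_B,FULL,RF,0.950,1.000,0.975,1.000,0.976
PC_B,FULL,SVM_L,0.975,1.000,0.988,1.000,0.987
PC_B,FULL,SVM_G,0.975,1.000,0.988,1.000,0.987
PC_B,FULL,SVM_P,0.950,1.000,0.975,1.000,0.976
PC_B,FULL,NB,0.925,0.925,0.925,0.925,0.925
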