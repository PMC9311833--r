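patient,state,role,mean,sd,n,n_subcortical
P1,interictal,hypo,0.51,0.07,2,1
P1,interictal,hyper,1.21,0.02,9,4
P1,ictal,hypo,0.41,0.14,3,2
P1,ictal,hyper,1.46,0.11,5,2
P1,change,hypo,-0.61,0.09,13,11
P1,change,hyper,0.27,0.11,11,6
P2,interictal,hypo,0.64,0.02,13,10
P2,interictal,hyper,1.24,0.04,4,0
P2,ictal,hypo,0.41,0.14,5,3
P2,ictal,hyper,1.29,0.07,14,9
P2,change,hypo,-0.13,0.05,19,2
P2,change,hyper,0.68,0.14,7,6
P3,interictal,hypo,0.45,0.11,7,7
P3,interictal,hyper,1.21,0.03,13,3
P3,ictal,hypo,0.46,0.11,7,6
P3,ictal,hyper,1.37,0.00,16,3
P3,change,hypo,-0.20,0.07,11,3
P3,change,hyper,0.37,0.12,7,2
P4,interictal,hypo,0.42,0.10,8,8
P4,interictal,hyper,1.16,0.00,9,1
P4,ictal,hypo,0.59,0.15,7,6
P4,ictal,hyper,1.30,0.06,4,3
P4,change,hypo,-0.12,0.04,9,1
P4,change,hyper,0.73,0.44,10,2
P5,interictal,hypo,0.57,0.08,7,7
P5,interictal,hyper,1.21,0.04,6,2
P5,ictal,hypo,0.45,0.08,4,4
P5,ictal,hyper,1.16,0.02,9,3
P5,change,hypo,-0.13,0.03,20,7
P5,change,hyper,0.27,0.07,4,2
P6,interictal,hypo,0.48,0.02,6,4
P6,interictal,hyper,1.33,0.04,6,3
P6,ictal,hypo,0.54,0.10,8,8
P6,ictal,hyper,1.28,0.10,14,3
P6,change,hypo,-0.47,0.10,2,2
P6,change,hyper,0.32,0.49,4,3
P7,interictal,hypo,0.60,0.01,3,3
P7,interictal,hyper,1.24,0.03,10,5
P7,ictal,hypo,0.50,0.14,7,6
P7,ictal,hyper,1.16,0.04,12,3
P7,change,hypo,-0.47,0.10,11,6
P7,change,hyper,0.11,0.03,14,3
P8,interictal,hypo,0.54,0.11,7,7
P8,interictal,hyper,1.16,0.04,10,1
P8,ictal,hypo,0.74,0.03,5,4
P8,ictal,hyper,1.44,0.09,4,4
P8,change,hypo,-0.11,0.04,24,6
P8,change,hyper,1.08,0.21,6,6
P9,interictal,hypo,0.62,0.06,4,3
P9,interictal,hyper,1.77,0.20,3,0
P9,ictal,hypo,0.57,0.02,4,3
P9,ictal,hyper,1.44,0.02,11,2
P9,change,hypo,-0.34,0.11,3,2
P9,change,hyper,0.25,0.09,15,3
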