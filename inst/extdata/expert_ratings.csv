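table,predictor,mean,sd,corrected
ti,0.005,86.31,6.28,88.1
ti,0.02,56.71,4.34,58.04
ti,10,10.23,1.03,8.94
ti,50,4.52,0.67,5.51
ti,50,4.52,0.67,5.51
ti,100,3.86,0.37,4.47
ti,200,3.09,0.42,3.63
ti,400,2.91,0.42,2.94
ti,750,2.3,0.36,2.44
ei,10,0.02,0.01,0.02
ei,30,0.07,0.02,0.07
ei,40,0.09,0.05,0.1
ei,48,0.12,0.05,0.11
ei,75,0.14,0.08,0.18
ei,225,0.53,0.11,0.52
ei,250,0.6,0.13,0.58
mi,0,0,0,0.18
mi,1,0.38,0.36,0.39
mi,2,0.59,0.06,0.6
mi,3,0.82,0.06,0.81
mi,4,1,0,1
pi,EEn+PPEn,0,0,0
pi,EEn+PPEe,0.18,0.06,0.18
pi,EEp+PPEn,0.42,0.03,0.42
pi,EEp+PPEe,0.61,0.12,0.61
pi,EEe+PPEn,0.74,0.04,0.74
pi,EEe+PPEe,1,0,1
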