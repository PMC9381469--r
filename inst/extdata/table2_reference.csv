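level,r2,slope,intercept,threshold_osteopenia,threshold_osteoporosis
C2,0.5772,1.253,90.15,240.5,190.4
C3,0.6282,1.266,100.7,252.6,202.0
C4,0.6434,1.350,101.2,263.2,209.2
C5,0.672,1.229,99.36,246.8,197.7
C6,0.7504,1.138,80.98,217.5,172.0
C7,0.688,0.9047,80.80,189.4,153.2
T1,0.7309,0.8606,54.50,157.8,123.3
T2,0.7698,0.8758,48.93,154.0,119.0
T3,0.7449,0.8591,39.86,143.0,108.6
T4,0.7605,0.8295,36.64,136.2,103.0
T5,0.7784,0.8132,34.69,132.3,99.7
T6,0.7805,0.8190,31.52,129.8,97.0
T7,0.7974,0.7929,32.59,127.7,96.0
T8,0.8266,0.8113,29.22,126.6,94.1
T9,0.8307,0.8357,28.50,128.8,95.4
T10,0.874,0.9000,23.01,131.0,95.0
T11,0.9069,0.9102,18.62,127.8,91.4
T12,0.9268,0.9303,9.346,121.0,83.8
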