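fold,mse,r2,adj_r2
1,18.54,0.406,0.400
2,22.06,0.011,0.001
3,12.56,0.538,0.534
4,13.07,0.546,0.541
5,13.58,0.559,0.555
6,10.22,0.661,0.657
7,12.81,0.537,0.533
8,16.68,0.485,0.480
9,11.06,0.567,0.563
10,16.36,0.456,0.451
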