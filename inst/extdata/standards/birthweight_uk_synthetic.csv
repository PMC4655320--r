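ga_weeks,sex,mean_g,sd_g
24,M,659.1,79.1
24,F,635,76.2
25,M,772.3,92.7
25,F,744,89.3
26,M,898.6,107.8
26,F,865.7,103.9
27,M,1038.2,124.6
27,F,1000.2,120
28,M,1191,142.9
28,F,1147.4,137.7
29,M,1356.6,162.8
29,F,1307,156.8
30,M,1534.4,184.1
30,F,1478.2,177.4
31,M,1723.2,206.8
31,F,1660.1,199.2
32,M,1921.6,230.6
32,F,1851.3,222.2
33,M,2127.7,255.3
33,F,2049.9,246
34,M,2339.4,280.7
34,F,2253.8,270.5
35,M,2553.9,306.5
35,F,2460.4,295.2
36,M,2768.4,332.2
36,F,2667.1,320.1
37,M,2979.8,357.6
37,F,2870.8,344.5
38,M,3184.7,382.2
38,F,3068.2,368.2
39,M,3379.7,405.6
39,F,3256,390.7
40,M,3561.3,427.4
40,F,3431,411.7
41,M,3726.1,447.1
41,F,3589.8,430.8
42,M,3871.2,464.5
42,F,3729.5,447.5
43,M,3993.4,479.2
43,F,3847.3,461.7
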