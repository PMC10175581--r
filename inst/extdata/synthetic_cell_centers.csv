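"id","x_um","y_um","marker"
1,73.12,499.65,"gfap"
2,44.08,529.91,"gfap"
3,154.05,288.76,"gfap"
4,500.55,505.27,"gfap"
5,214.92,241.39,"gfap"
6,614.34,480.13,"gfap"
7,104.82,276.04,"gfap"
8,290.15,571.47,"gfap"
9,108.54,201.95,"gfap"
10,146.29,52.18,"gfap"
11,488.42,515.89,"gfap"
12,60.86,567.84,"gfap"
13,286.58,610.83,"gfap"
14,53.53,362.18,"gfap"
15,354.34,455.09,"gfap"
16,5.5,489.21,"gfap"
17,622.99,396.74,"gfap"
18,200.08,456.93,"gfap"
19,404.13,244.48,"gfap"
20,186.58,102.88,"gfap"
21,629.92,118.33,"gfap"
22,572.61,247.27,"gfap"
23,624.88,173.11,"gfap"
24,41.49,121.29,"gfap"
25,396.29,318.78,"gfap"
26,309.98,482.75,"gfap"
27,613.69,438.4,"gfap"
28,228.92,343.84,"gfap"
29,429.76,416.54,"gfap"
30,166.67,296.24,"gfap"
31,117.37,304.5,"gfap"
32,117.01,213.02,"gfap"
33,239.72,268.3,"gfap"
34,535.32,181.39,"gfap"
35,314.78,379.95,"gfap"
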