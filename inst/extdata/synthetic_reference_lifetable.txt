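Age    qx        lx           Lx
15     0.00030   100000.00    99985.00
16     0.00033   99970.00     99953.50
17     0.00036   99937.01     99919.02
18     0.00040   99901.03     99881.05
19     0.00044   99861.07     99839.10
20     0.00048   99817.13     99793.18
21     0.00053   99769.22     99742.78
22     0.00058   99716.34     99687.43
23     0.00064   99658.51     99626.62
24     0.00071   99594.73     99559.37
25     0.00078   99524.01     99485.20
26     0.00085   99446.39     99404.12
27     0.00094   99361.86     99315.16
28     0.00103   99268.46     99217.33
29     0.00113   99166.21     99110.18
30     0.00125   99054.15     98992.24
31     0.00137   98930.33     98862.57
32     0.00151   98794.80     98720.21
33     0.00166   98645.62     98563.74
34     0.00182   98481.87     98392.25
35     0.00201   98302.63     98203.84
36     0.00221   98105.04     97996.64
37     0.00243   97888.23     97769.30
38     0.00267   97650.36     97520.00
39     0.00293   97389.64     97246.96
40     0.00323   97104.28     96947.46
41     0.00355   96790.64     96618.83
42     0.00390   96447.03     96258.96
43     0.00429   96070.89     95864.81
44     0.00472   95658.74     95432.99
45     0.00519   95207.23     94960.17
46     0.00570   94713.11     94443.18
47     0.00627   94173.24     93878.01
48     0.00690   93582.78     93259.92
49     0.00758   92937.06     92584.82
50     0.00834   92232.59     91847.98
51     0.00917   91463.37     91044.01
52     0.01008   90624.65     90167.91
53     0.01109   89711.16     89213.71
54     0.01220   88716.26     88175.09
55     0.01341   87633.92     87046.34
56     0.01475   86458.75     85821.12
57     0.01622   85183.48     84492.65
58     0.01783   83801.81     83054.72
59     0.01961   82307.62     81500.60
60     0.02156   80693.57     79823.69
61     0.02371   78953.82     78017.82
62     0.02608   77081.82     76076.67
63     0.02868   75071.53     73995.00
64     0.03153   72918.48     71768.92
65     0.03468   70619.36     69394.82
66     0.03813   68170.28     66870.61
67     0.04193   65570.94     64196.25
68     0.04611   62821.55     61373.20
69     0.05071   59924.85     58405.46
70     0.05576   56886.06     55300.08
71     0.06132   53714.10     52067.22
72     0.06743   50420.35     48720.43
73     0.07415   47020.50     45277.22
74     0.08153   43533.93     41759.27
75     0.08966   39984.61     38192.10
76     0.09860   36399.59     34605.09
77     0.10842   32810.59     31031.93
78     0.11923   29253.27     27509.33
79     0.13111   25765.40     24076.35
80     0.14417   22387.30     20773.51
81     0.15854   19159.72     17640.93
82     0.17434   16122.14     14716.77
83     0.19172   13311.41     12035.37
84     0.21082   10759.34     9625.20
85     0.23184   8491.06      7506.77
86     0.25494   6522.49      5691.07
87     0.28035   4859.65      4178.45
88     0.30829   3497.25      2958.16
89     0.33901   2419.08      2009.03
90     0.37279   1598.99      1300.94
91     0.40995   1002.90      797.33
92     0.45080   591.76       458.38
93     0.49573   325.00       244.44
94     0.54513   163.89       119.22
95     0.59946   74.55        52.20
96     0.65920   29.86        20.02
97     0.72490   10.18        6.49
98     0.79714   2.80         1.68
99     0.87658   0.57         0.32
100    0.96394   0.07         0.04
101    1.00000   0.00         0.00
102    1.00000   0.00         0.00
103    1.00000   0.00         0.00
104    1.00000   0.00         0.00
105    1.00000   0.00         0.00
106    1.00000   0.00         0.00
107    1.00000   0.00         0.00
108    1.00000   0.00         0.00
109    1.00000   0.00         0.00
110+   1.00000   0.00         0.00
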