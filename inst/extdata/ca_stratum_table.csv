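age_bin,gender,adl,cognition,falls,pct
<50,1,1,1,1,0.06
50-64,1,1,1,1,0.16
65-74,1,1,1,1,0.15
75-84,1,1,1,1,0.20
>84,1,1,1,1,0.09
<50,1,1,1,0,0.39
50-64,1,1,1,0,0.41
65-74,1,1,1,0,0.73
75-84,1,1,1,0,2.12
>84,1,1,1,0,1.68
<50,1,1,0,1,0.39
50-64,1,1,0,1,0.60
65-74,1,1,0,1,0.38
75-84,1,1,0,1,0.36
>84,1,1,0,1,0.10
<50,1,1,0,0,0.72
50-64,1,1,0,0,1.57
65-74,1,1,0,0,2.00
75-84,1,1,0,0,3.57
>84,1,1,0,0,2.12
<50,1,0,1,1,0.09
50-64,1,0,1,1,0.11
65-74,1,0,1,1,0.05
75-84,1,0,1,1,0.08
>84,1,0,1,1,0.01
<50,1,0,1,0,0.14
50-64,1,0,1,0,0.18
65-74,1,0,1,0,0.23
75-84,1,0,1,0,0.62
>84,1,0,1,0,0.44
<50,1,0,0,1,2.09
50-64,1,0,0,1,1.79
65-74,1,0,0,1,0.72
75-84,1,0,0,1,0.44
>84,1,0,0,1,0.09
<50,1,0,0,0,3.32
50-64,1,0,0,0,4.41
65-74,1,0,0,0,3.76
75-84,1,0,0,0,4.37
>84,1,0,0,0,1.84
<50,0,1,1,1,0.05
50-64,0,1,1,1,0.13
65-74,0,1,1,1,0.11
75-84,0,1,1,1,0.24
>84,0,1,1,1,0.11
<50,0,1,1,0,0.41
50-64,0,1,1,0,0.46
65-74,0,1,1,0,0.69
75-84,0,1,1,0,2.82
>84,0,1,1,0,3.56
<50,0,1,0,1,0.46
50-64,0,1,0,1,0.70
65-74,0,1,0,1,0.48
75-84,0,1,0,1,0.56
>84,0,1,0,1,0.16
<50,0,1,0,0,1.23
50-64,0,1,0,0,2.44
65-74,0,1,0,0,2.99
75-84,0,1,0,0,6.36
>84,0,1,0,0,5.02
<50,0,0,1,1,0.07
50-64,0,0,1,1,0.08
65-74,0,0,1,1,0.05
75-84,0,0,1,1,0.09
>84,0,0,1,1,0.03
<50,0,0,1,0,0.16
50-64,0,0,1,0,0.15
65-74,0,0,1,0,0.23
75-84,0,0,1,0,0.89
>84,0,0,1,0,0.70
<50,0,0,0,1,1.96
50-64,0,0,0,1,1.43
65-74,0,0,0,1,0.56
75-84,0,0,0,1,0.47
>84,0,0,0,1,0.10
<50,0,0,0,0,4.62
50-64,0,0,0,0,4.84
65-74,0,0,0,0,3.81
75-84,0,0,0,0,5.39
>84,0,0,0,0,2.81
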