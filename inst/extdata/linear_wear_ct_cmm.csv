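cup,ct_mean,ct_sd,cmm_mean,cmm_sd,printed_difference,soak_control
1,0.65,0.14,1.55,0.21,-0.90,FALSE
2,0.89,0.15,1.23,0.06,-0.34,FALSE
3,0.81,0.11,1.15,0.16,-0.34,FALSE
4,0.20,0.16,0.08,0.14,0.12,TRUE
5,2.22,0.12,2.54,0.27,-0.32,FALSE
6,2.18,0.13,1.69,0.25,0.49,FALSE
7,0.01,0.14,0.02,0.23,-0.00,TRUE
8,0.17,0.07,0.02,0.24,0.15,TRUE
9,1.00,0.12,1.26,0.09,-0.26,FALSE
10,-0.01,0.10,0.05,0.08,-0.06,TRUE
11,0.46,0.12,0.60,0.08,-0.14,FALSE
12,1.04,0.14,0.91,0.13,0.13,FALSE
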