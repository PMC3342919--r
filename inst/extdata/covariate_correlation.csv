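variable,pct_college,smoking_rate,obesity_rate,physicians_per_1000,poverty_rate,pct_black,pct_native,pct_hispanic,pct_asian,pct_other
pct_college,1,-0.42,-0.385,0.14,-0.525,-0.245,-0.105,-0.07,0.175,-0.07
smoking_rate,-0.42,1,0.33,-0.12,0.45,0.21,0.09,0.06,-0.15,0.06
obesity_rate,-0.385,0.33,1,-0.11,0.4125,0.1925,0.0825,0.055,-0.1375,0.055
physicians_per_1000,0.14,-0.12,-0.11,1,-0.15,-0.07,-0.03,-0.02,0.05,-0.02
poverty_rate,-0.525,0.45,0.4125,-0.15,1,0.2625,0.1125,0.075,-0.1875,0.075
pct_black,-0.245,0.21,0.1925,-0.07,0.2625,1,0.0525,0.035,-0.0875,0.035
pct_native,-0.105,0.09,0.0825,-0.03,0.1125,0.0525,1,0.015,-0.0375,0.015
pct_hispanic,-0.07,0.06,0.055,-0.02,0.075,0.035,0.015,1,-0.025,0.01
pct_asian,0.175,-0.15,-0.1375,0.05,-0.1875,-0.0875,-0.0375,-0.025,1,-0.025
pct_other,-0.07,0.06,0.055,-0.02,0.075,0.035,0.015,0.01,-0.025,1
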