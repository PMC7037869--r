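department,R,C,R_minus_C
ED20,0.5965,1.2435,-0.647
ED19,0.4613,1.3916,-0.930
ED18,0.4537,1.3638,-0.910
ED17,0.3622,1.2963,-0.934
ED16,1.6005,1.48,0.1158
ED15,2.2539,2.23,0.0156
ED14,1.8993,2.46,-0.569
ED13,1.9511,2.42,-0.469
ED12,0.5358,2.20,-1.669
ED11,3.1807,2.57,0.6089
ED10,3.1807,2.57,0.6089
ED9,1.9383,2.05,-0.116
ED8,1.9383,1.9971,-0.058
ED7,1.5729,2.39,-0.824
ED6,3.8839,2.47,1.4116
ED5,3.8916,2.47,1.4193
ED4,3.8917,2.48,1.4092
ED3,2.7805,2.24,0.5329
ED2,2.7858,2.28,0.5041
ED1,2.7858,2.2816,0.5041
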