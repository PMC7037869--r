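department,ws
ED20,36.5
ED19,25.67
ED18,42.25
ED17,43.07
ED16,36.05
ED15,24.45
ED14,36.03
ED13,30.57
ED12,35.10
ED11,41.46
ED10,43.56
ED9,22.23
ED8,23.22
ED7,36.04
ED6,28.22
ED5,28.96
ED4,28.08
ED3,24.63
ED2,21.10
ED1,21.10
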