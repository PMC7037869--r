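criterion_id,raw_weight
MR1,0.07211
MR2,0.11057
MR3,0.10817
MR4,0.10336
MR5,0.05528
MR6,0.06971
MR7,0.06971
MR8,0.04086
MR9,0.06490
MR10,0.40865
MR11,0.09855
MR12,0.04567
Infection Risk,0.12019
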