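SLC22A8
SLCO1B3
QLQX-9
QLQX-11
QLQX-5
QLQX-8
CYP1A1
QLQX-12
QLQX-6
ATP1A1
VEGFA
CYP2B6
STAT3
SLCO1A2
QLQX-10
QLQX-4
STAT4
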