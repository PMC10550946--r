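composition,common_name
N1,Tn (GalNAc)
N1A1,sialyl-Tn
N1H1,core 1 (T antigen)
N1H1A1,monosialyl core 1
N1H1A2,disialyl core 1
N1H1F1,fucosyl core 1
N2,di-HexNAc
N2H1,core 2
N2H2,extended core 2
N2H2A1,monosialyl core 2
N2H2A2,disialyl core 2
N2H2F1,fucosyl core 2
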