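symbol,name,formula,mass
N,HexNAc (GalNAc),C8H13NO5,203.07937252
H,Hexose (galactose),C6H10O5,162.05282342
A,NeuAc (sialic acid),C11H17NO8,291.09541651
F,Fucose (dHex),C6H10O4,146.05790880
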