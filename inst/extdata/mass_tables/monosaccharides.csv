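unit,formula
Hex,C6H10O5
HexNAc,C8H13N1O5
Fuc,C6H10O4
Neu5Ac,C11H17N1O8
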