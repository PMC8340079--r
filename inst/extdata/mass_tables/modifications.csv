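modification,formula
water,H2O1
carbamidomethyl,C2H3N1O1
oxidation,O1
deamidation,H-1N-1O1
disulfide,H-2
sodium_adduct,Na1H-1
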