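element,monoisotopic,average
H,1.00782503207,1.008
C,12.0,12.011
N,14.0030740048,14.007
O,15.9949146196,15.999
S,31.97207100,32.06
Na,22.98976928,22.98976928
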