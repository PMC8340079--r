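>hCGalpha mature glycoprotein hormones alpha chain (92 aa)
APDVQDCPECTLQENPFFSQPGAPILQCMGCCFSRAYPTPLRSKKTMLVQKNVTSESTCC
VAKSYNRVTVMGGFKVENHTACHCSTCYYHKS
>hCGbeta mature choriogonadotropin beta subunit (145 aa)
SKEPLRPRCRPINATLAVEKEGCPVCITVNTTICAGYCPTMTRVLQGVLPALPQVVCNYR
DVRFESIRLPGCPRGVNPVVSYAVALSCQCALCRRSTTDCGGPKDHPLTCDDPRFQDSSS
SKAPPPSLPSPSRLPGPSDTPILPQ
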