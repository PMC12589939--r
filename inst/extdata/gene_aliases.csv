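alias,symbol
ACPP,ACP3
SEPT14,SEPTIN14
KIAA1598,SHTN1
MLL,KMT2A
C11ORF95,ZFTA
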