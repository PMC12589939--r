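driver,partner
ALK,EML4
ALK,KIF5B
ALK,TFG
RET,CCDC6
RET,KIF5B
RET,NCOA4
ROS1,CD74
ROS1,EZR
ROS1,SLC34A2
NTRK1,TPM3
NTRK1,LMNA
NTRK2,SQSTM1
NTRK2,TRIM24
NTRK3,ETV6
FGFR2,BICC1
FGFR2,TACC3
FGFR2,ACP3
FGFR3,TACC3
NRG1,CD74
NRG1,ATP1B1
NRG1,SLC3A2
NRG1,RBPMS
BRAF,AGK
BRAF,SND1
BRAF,KIAA1549
EGFR,SEPTIN14
EGFR,VOPP1
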