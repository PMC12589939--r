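driver,cancer_type,status
RET,*,approved
NTRK1,*,approved
NTRK2,*,approved
NTRK3,*,approved
ALK,NSCLC,approved
ROS1,NSCLC,approved
FGFR2,cholangiocarcinoma,approved
FGFR3,urothelial,approved
NRG1,NSCLC,approved
NRG1,pancreatic,approved
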