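driver,retained_side,chrom,domain_start,domain_end
ALK,3p,2,29420000,29445000
RET,3p,10,43609928,43625000
ROS1,3p,6,117610000,117650000
NTRK1,3p,1,156830000,156851000
NTRK2,3p,9,87475000,87563000
NTRK3,3p,15,88420000,88520000
FGFR2,5p,10,123240000,123280000
FGFR3,5p,4,1795000,1808000
NRG1,3p,8,32405000,32460000
BRAF,3p,7,140430000,140482000
EGFR,5p,7,55086000,55224000
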