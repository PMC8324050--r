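reaction_id	lower	upper
EX_mal	-4	0
EX_succ	0	0
EX_sucr	0	0
EX_glc	0	0
EX_ara	0	0
EX_gaba	0	0
EX_o2	-4	0
EX_n2	-1000	0
EX_nh3	0	1000
EX_ala	0	1000
EX_asp	0	1000
EX_co2	0	1000
EX_h2	0	1000
EX_h2o	-1000	1000
DM_glu	0.01	0.05
DM_gln	0.01	0.05
DM_ala	0.01	1000
DM_asp	0.01	1000
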