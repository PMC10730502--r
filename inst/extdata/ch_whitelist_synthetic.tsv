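gene	rule_kind	detail	source
DNMT3A	any_truncating		synthetic curation of canonical CH drivers
DNMT3A	listed_missense_positions	882,635,688,736,771,543	synthetic curation of canonical CH drivers
TET2	any_truncating		synthetic curation of canonical CH drivers
TET2	listed_missense_positions	1863,1868,1382	synthetic curation of canonical CH drivers
ASXL1	any_truncating		synthetic curation of canonical CH drivers
PPM1D	any_truncating		synthetic curation of canonical CH drivers
TP53	any		synthetic curation of canonical CH drivers
JAK2	hotspot_codon_set	617	synthetic curation of canonical CH drivers
SF3B1	listed_missense_positions	700,666,625	synthetic curation of canonical CH drivers
SRSF2	hotspot_codon_set	95	synthetic curation of canonical CH drivers
IDH1	hotspot_codon_set	132	synthetic curation of canonical CH drivers
IDH2	hotspot_codon_set	140,172	synthetic curation of canonical CH drivers
CBL	listed_missense_positions	366,381,384,404,420	synthetic curation of canonical CH drivers
GNB1	hotspot_codon_set	57	synthetic curation of canonical CH drivers
GNAS	hotspot_codon_set	201,844	synthetic curation of canonical CH drivers
STAT3	listed_missense_positions	614,647,661	synthetic curation of canonical CH drivers
MYD88	hotspot_codon_set	265	synthetic curation of canonical CH drivers
KRAS	hotspot_codon_set	12,13,61	synthetic curation of canonical CH drivers
NRAS	hotspot_codon_set	12,13,61	synthetic curation of canonical CH drivers
CHEK2	any_truncating		synthetic curation of canonical CH drivers
RAD21	any_truncating		synthetic curation of canonical CH drivers
STAG2	any_truncating		synthetic curation of canonical CH drivers
BCOR	any_truncating		synthetic curation of canonical CH drivers
BCORL1	any_truncating		synthetic curation of canonical CH drivers
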