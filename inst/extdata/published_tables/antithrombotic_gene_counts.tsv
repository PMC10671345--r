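# Transcription of the published per-family antithrombotic gene counts for
# Hirudinaria manillensis: two earlier genome surveys (Guan et al. 2019;
# Zheng et al. 2022) and the BRAKER / BRAKER-plus predictions of a
# chromosome-scale genome survey. Cells are verbatim; printed column
# totals were 28 / 46 / 61 / 72 (the zheng2022 cells sum to 45, one less
# than its printed total -- recorded, not reconciled).
family	guan2019	zheng2022	braker	braker_plus
hirudin	1	3	3	5
granulin	1	1	1	1
antistasin	0	2	2	2
lefaxin	3	3	3	3
therostasin	0	1	0	1
hirustasin	1	1	1	1
hirustasin-like	3	5	11	12
guamerin	0	0	1	1
piguamerin	0	0	1	1
bdellastasin	0	1	1	1
poecistasin	0	1	0	2
eglin	0	3	3	4
bdellin	0	0	0	1
LDTI	1	1	1	1
HMEI	4	9	15	18
saratin	1	1	2	2
apyrase	5	5	5	5
lumbrokinase	3	3	3	3
destabilase	0	1	3	3
GGT	1	1	1	1
LCI	1	0	1	1
hyaluronidase	3	3	3	3
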