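# Published per-chromosome accounting of opossum-human conserved synteny blocks
# (species-A = opossum). Chromosomes 4 and 7 were covered by earlier mapping
# studies; the six newly analysed autosomes are 1, 2, 3, 5, 6 and 8.
chromosome	n_blocks	smallest_mb	largest_mb	mean_mb	newly_analysed
1	48	0.2	83	15	yes
2	22	0.3	168	24	yes
3	22	0.07	82	23	yes
4	18	0.7	117	117	no
5	5	1.6	218	60.3	yes
6	38	0.03	48	7.4	yes
7	12	0.2	95	21.2	no
8	19	1	87	15.5	yes
X	24	0.14	9.7	1.9	no
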