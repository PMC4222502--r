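# Arrangement of the conserved chromosome segments (painting alphabet C1-C18
# plus X; C1 and C4 split into a/b sub-segments where interleaved) in six
# marsupials, plus a chicken-derived outgroup adjacency proxy.
#
# Provenance per line:
#   [stated]        arrangement stated verbatim in the comparative-mapping
#                   literature for this species
#   [reconstructed-from-literature]  assembled here from qualitative
#                   statements (which segments share a chromosome, which
#                   fusions are present/absent); order/orientation within the
#                   chromosome is a representative choice, not an observation
#   [synthetic]     proxy encoding, not a real karyotype
#
# S. crassicaudata (fat-tailed dunnart), 2n = 14
S_crassicaudata	chr1	C2 C1a C4a C3 C1b C4b C5 C6
# ^ [stated]
S_crassicaudata	chr2	C13 C14
# ^ [reconstructed-from-literature] C13+C14 joined in most marsupials
S_crassicaudata	chr3	C10 C12 C11
# ^ [stated]
S_crassicaudata	chr4	C8 C7 C9
# ^ [reconstructed-from-literature] C8-C7-C9 arrangement of 2n=14 species
S_crassicaudata	chr5	C15 C16
# ^ [reconstructed-from-literature] C15+C16 adjacent in all but A. rufescens
S_crassicaudata	chr6	C17 C18
# ^ [reconstructed-from-literature] C17+C18 fused outside macropodiformes
S_crassicaudata	chrX	X
#
# M. eugenii (tammar wallaby), 2n = 16
M_eugenii	chr1	C1a C1b C8 C9
# ^ [reconstructed-from-literature] C1 on 1p; C8 and C9 on 1q with a direct
#   C8|C9 junction (C7 absent from this chromosome)
M_eugenii	chr2	C13 C14
M_eugenii	chr3	C2 C3 C15 C16
# ^ [reconstructed-from-literature] C2/C3 rearranged material plus C15 and
#   terminal C16 on 3q
M_eugenii	chr4	C4a C4b C5 C6
# ^ [reconstructed-from-literature] C4, C5, C6 share chromosome 4
M_eugenii	chr5	C12 C11
M_eugenii	chr6	C10
M_eugenii	chr7	C17 C7 C18
# ^ [reconstructed-from-literature] C7 is an entire arm of chromosome 7;
#   C17 and C18 also on 7 but not fused in macropodiformes
M_eugenii	chrX	X
#
# A. rufescens (rufous bettong), 2n = 32; painting probes derive from this
# species, so most segments are whole chromosomes
A_rufescens	chr1	C1a C1b
A_rufescens	chr2	C2
A_rufescens	chr3	C3
A_rufescens	chr4	C4a C4b
A_rufescens	chr5	C5 C6
A_rufescens	chr6	C7
A_rufescens	chr7	C8
A_rufescens	chr8	C9
A_rufescens	chr9	C10
A_rufescens	chr10	C12 C11
A_rufescens	chr11	C13 C14
A_rufescens	chr12	C15
A_rufescens	chr13	C16
A_rufescens	chr14	C17
A_rufescens	chr15	C18
A_rufescens	chrX	X
# ^ all [reconstructed-from-literature]; C15|C16 fission and separate
#   C17/C18 are stated for this species
#
# T. vulpecula (brushtail possum), 2n = 20
T_vulpecula	chr1	C2 C1a C4a C3
T_vulpecula	chr2	C1b C4b C5 C6
T_vulpecula	chr3	C13
T_vulpecula	chr4	C14
# ^ C13/C14 separation [stated] for this species
T_vulpecula	chr5	C10 C12
T_vulpecula	chr6	C8 C7 C9
T_vulpecula	chr7	C15 C16
T_vulpecula	chr8	C17 C18
T_vulpecula	chr9	C11
T_vulpecula	chrX	X
# ^ remainder [reconstructed-from-literature]
#
# M. domestica (grey short-tailed opossum), 2n = 18
M_domestica	chr1	C8 C7 C9
# ^ [stated] C7 lies between C8 and C9 on opossum chromosome 1
M_domestica	chr2	C13 C14
# ^ [stated]
M_domestica	chr3	C4a C4b C5 C6
M_domestica	chr4	C11
# ^ [stated]
M_domestica	chr5	C15 C16
M_domestica	chr6	C2 C1a C3 C1b
# ^ [stated in part] C1 material interleaved with C2 and C3 genes on
#   chromosome 6
M_domestica	chr7	C10 C12
# ^ [stated]
M_domestica	chr8	C17 C18
M_domestica	chrX	X
#
# D. marsupialis (common opossum), 2n = 22 (predicted from G-banding)
D_marsupialis	chr1	C4a C4b C5 C6
# ^ [stated] chromosome 1 consists of C4-C5-C6
D_marsupialis	chr2	C9
# ^ [stated] C9 makes up the entire chromosome 2
D_marsupialis	chr3	C10 C12
D_marsupialis	chr4	C11
D_marsupialis	chr5	C13
D_marsupialis	chr6	C14
# ^ C13/C14 separation [stated] for this species
D_marsupialis	chr7	C15 C16
D_marsupialis	chr8	C3 C1a C1b C2
# ^ [stated] chromosome 8 consists of C3-C1-C2
D_marsupialis	chr9	C17 C18
D_marsupialis	chr10	C8 C7
# ^ [reconstructed-from-literature]
D_marsupialis	chrX	X
#
# chicken: [synthetic] outgroup adjacency proxy. Not the chicken karyotype;
# each line encodes one outgroup-supported linkage derived from chicken gene
# order (C10-C12-C11; the C1-C6 chain; C8-C7-C9; C13-C14; C15-C16; C17-C18).
chicken	g1	C10 C12 C11
chicken	g2	C2 C1a C4a C3 C1b C4b C5 C6
chicken	g3	C8 C7 C9
chicken	g4	C13 C14
chicken	g5	C15 C16
chicken	g6	C17 C18
chicken	gZ	X
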