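# Published per-chromosome accounting of genes mapped to tammar wallaby
# chromosomes: FISH assignments from the wallaby mapping study (current) and
# previously published assignments (previous). Predicted sizes are
# pass-through metadata.
chromosome	predicted_size_mb	n_current	n_previous
1	486	54	11
2	367	47	44
3	355	76	7
4	340	36	4
5	340	0	141
6	286	7	28
7	133	13	4
X	150	9	73
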