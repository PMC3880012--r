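chrom	length_bp
chr1	60348388
chr2	60300536
chr3	63268876
chr4	62094675
chr5	75682077
chr6	59938731
chr7	77276063
chr8	56184765
chr9	58232459
chr10	46591166
chr11	46661319
chr12	50697278
chr13	54093808
chr14	53733891
chr15	47442429
chr16	58780683
chr17	53984731
chr18	49877488
chr19	50254551
chr20	55952140
chr21	44544065
chr22	42261000
chr23	46386876
chr24	43947580
chr25	38499472
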