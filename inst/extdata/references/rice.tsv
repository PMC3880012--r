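chrom	length_bp
chr1	43268879
chr2	35930381
chr3	36406689
chr4	35278225
chr5	29894789
chr6	31246789
chr7	29696629
chr8	28439308
chr9	23011239
chr10	22876596
chr11	28462103
chr12	27497214
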