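chrom	length_bp
SL2.40ch01	90304244
SL2.40ch02	49918294
SL2.40ch03	64840714
SL2.40ch04	64064312
SL2.40ch05	65021438
SL2.40ch06	46041636
SL2.40ch07	65268621
SL2.40ch08	63032657
SL2.40ch09	67662091
SL2.40ch10	64834305
SL2.40ch11	53386025
SL2.40ch12	65486253
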