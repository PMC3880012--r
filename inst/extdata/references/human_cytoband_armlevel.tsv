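chrom	start	end	band	stain
chr1	1	122000000	p	gneg
chr1	122000001	128000000	cen	acen
chr1	128000001	249250621	q	gpos50
chr2	1	90300000	p	gneg
chr2	90300001	96300000	cen	acen
chr2	96300001	243199373	q	gpos50
chr3	1	88000000	p	gneg
chr3	88000001	94000000	cen	acen
chr3	94000001	198022430	q	gpos50
chr4	1	47400000	p	gneg
chr4	47400001	53400000	cen	acen
chr4	53400001	191154276	q	gpos50
chr5	1	45400000	p	gneg
chr5	45400001	51400000	cen	acen
chr5	51400001	180915260	q	gpos50
chr6	1	58000000	p	gneg
chr6	58000001	64000000	cen	acen
chr6	64000001	171115067	q	gpos50
chr7	1	56900000	p	gneg
chr7	56900001	62900000	cen	acen
chr7	62900001	159138663	q	gpos50
chr8	1	42600000	p	gneg
chr8	42600001	48600000	cen	acen
chr8	48600001	146364022	q	gpos50
chr9	1	46000000	p	gneg
chr9	46000001	52000000	cen	acen
chr9	52000001	141213431	q	gpos50
chr10	1	37200000	p	gneg
chr10	37200001	43200000	cen	acen
chr10	43200001	135534747	q	gpos50
chr11	1	50700000	p	gneg
chr11	50700001	56700000	cen	acen
chr11	56700001	135006516	q	gpos50
chr12	1	32800000	p	gneg
chr12	32800001	38800000	cen	acen
chr12	38800001	133851895	q	gpos50
chr13	1	14900000	p	gneg
chr13	14900001	20900000	cen	acen
chr13	20900001	115169878	q	gpos50
chr14	1	14600000	p	gneg
chr14	14600001	20600000	cen	acen
chr14	20600001	107349540	q	gpos50
chr15	1	16000000	p	gneg
chr15	16000001	22000000	cen	acen
chr15	22000001	102531392	q	gpos50
chr16	1	33600000	p	gneg
chr16	33600001	39600000	cen	acen
chr16	39600001	90354753	q	gpos50
chr17	1	21000000	p	gneg
chr17	21000001	27000000	cen	acen
chr17	27000001	81195210	q	gpos50
chr18	1	14200000	p	gneg
chr18	14200001	20200000	cen	acen
chr18	20200001	78077248	q	gpos50
chr19	1	23500000	p	gneg
chr19	23500001	29500000	cen	acen
chr19	29500001	59128983	q	gpos50
chr20	1	24500000	p	gneg
chr20	24500001	30500000	cen	acen
chr20	30500001	63025520	q	gpos50
chr21	1	10200000	p	gneg
chr21	10200001	16200000	cen	acen
chr21	16200001	48129895	q	gpos50
chr22	1	11700000	p	gneg
chr22	11700001	17700000	cen	acen
chr22	17700001	51304566	q	gpos50
chrX	1	57600000	p	gneg
chrX	57600001	63600000	cen	acen
chrX	63600001	155270560	q	gpos50
chrY	1	9500000	p	gneg
chrY	9500001	15500000	cen	acen
chrY	15500001	59373566	q	gpos50
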