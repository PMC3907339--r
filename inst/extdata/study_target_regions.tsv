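locus	chrom	roi_kb
CELSR2	1	36.464
GALNT2	1	4.530
GCKR	2	2.189
ABCG8	2	38.183
G6PC2	2	17.240
LPL	8	3.747
ABCA1	9	11.176
PANK1	10	3.684
CRY2	11	10.997
MADD	11	47.317
FADS1	11	9.273
MTNR1B	11	1.662
APOA1	11	5.057
MVK	12	6.093
LIPC	15	2.175
CETP	16	16.686
NCAN	19	55.570
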