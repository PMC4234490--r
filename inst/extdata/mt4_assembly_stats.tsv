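seqid	real	ns	total	pct_real_printed
chr1	50275726	2715429	52991155	94.9
chr2	43694219	2035453	45729672	95.5
chr3	52386245	3128907	55515152	94.4
chr4	54533855	2048528	56582383	96.4
chr5	43376507	254224	43630731	99.4
chr6	31992419	3283294	35275713	90.7
chr7	46512325	2660098	49172423	94.6
chr8	43183948	2386037	45569985	94.8
chr total	365955244	18511970	384467214	95.2
Unplaced	24050008	4319556	28369564	84.8
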