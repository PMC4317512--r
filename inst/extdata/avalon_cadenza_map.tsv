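locus_id	chromosome	pos_cM
qEM-psr-1B.2	1B	45
qEM-psr-1D.1	1D	60
qPH-psr-2A.1	2A	10
qTRSA-2A	2A	160
Yr7	2B	70
qGY-psr-2D.1	2D	55
qGY-psr-3A.2	3A	10
qPH-psr-3A	3A	160
qGY-psr-3B.2	3B	10
qPH-psr-3B.1	3B	160
qPH-psr-4D	4D	30
qGRL-psr-5A.1	5A	0
qTGW-psr-5A.1	5A	80
qEM-psr-5A	5A	155
qPH-psr-5A.1	5A	240
qSDW-5A	5A	318
qGRW-psr-5A.2	5A	396
Vrn-A1b	5A	481
qTRL-5B	5B	50
Sbm1-5D	5D	40
qEM-psr-6A.1	6A	10
qTRL-6A	6A	160
Yr6	7B	65
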