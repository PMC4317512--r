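locus_id	DH27	DH61	DH182	DH109	DH160	target
qGY-psr-2D.1	CC	AA	CC	CC	AA	CC
qGY-psr-3A.2	AA	CC	AA	CC	AA	CC
qGY-psr-3B.2	CC	AA	AA	AA	AA	AA
qTGW-psr-5A.1	CC	AA	CC	AA	CC	CC
qGRL-psr-5A.1	CC	AA	CC	CC	CC	CC
qGRW-psr-5A.2	AA	AA	AA	AA	CC	AA
qPH-psr-2A.1	CC	AA	AA	CC	AA	AA
qPH-psr-3A	AA	AA	CC	AA	AA	AA
qPH-psr-3B.1	CC	CC	AA	CC	AA	CC
qPH-psr-4D	AA	AA	AA	AA	AA	AA
qPH-psr-5A.1	CC	AA	CC	AA	CC	AA
qEM-psr-1B.2	CC	AA	CC	CC	CC	CC
qEM-psr-1D.1	AA	AA	AA	AA	AA	AA
qEM-psr-5A	AA	CC	AA	AA	CC	CC
qEM-psr-6A.1	CC	AA	AA	CC	AA	AA
Vrn-A1b	CC	AA	AA	CC	AA	AA
qTRSA-2A	CC	AA	CC	AA	CC	CC
qSDW-5A	CC	AA	CC	CC	CC	CC
qTRL-5B	CC	CC	CC	CC	AA	CC
qTRL-6A	CC	AA	AA	CC	AA	AA
Sbm1-5D	CC	CC	CC	CC	AA	CC
Yr6	CC	AA	CC	AA	CC	CC
Yr7	CC	CC	AA	CC	AA	CC
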