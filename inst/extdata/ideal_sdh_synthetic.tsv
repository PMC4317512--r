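locus_id	SDH1	SDH2	SDH3	SDH4	SDH5	SDH6	SDH7	SDH8	SDH9
qGY-psr-2D.1	C	C	C	C	C	C	C	C	C
qGY-psr-3A.2	C	C	C	C	C	C	C	C	C
qGY-psr-3B.2	A	A	A	A	A	A	A	A	A
qPH-psr-2A.1	C	C	A	C	C	C	A	A	C
qPH-psr-2D	C	C	C	C	C	C	C	C	C
qPH-psr-3A	A	A	C	C	C	A	A	C	C
qPH-psr-3B.1	C	C	C	A	A	A	C	C	C
qPH-psr-4D	A	A	A	A	A	A	A	A	A
qPH-psr-5A.1	A	A	A	C	C	A	C	A	C
qEM-psr-1B.2	A	A	A	A	A	C	A	A	A
qEM-psr-1D.1	A	A	A	A	A	A	A	A	C
qEM-psr-3A	A	C	C	C	A	A	A	A	C
qEM-psr-5A	A	A	A	C	C	A	A	A	A
qEM-psr-6A.1	A	A	A	A	A	A	C	A	A
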