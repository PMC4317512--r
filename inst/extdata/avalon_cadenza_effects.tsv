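locus_id	trait	environment	additive_effect	increasing_parent	provenance
qGY-psr-2D.1	GY	MET	0.37	C	paper
qGY-psr-2D.1	GY	2005	0.42	C	synthetic
qGY-psr-2D.1	GY	2006	-0.08	C	synthetic
qGY-psr-2D.1	GY	2007	0.55	C	synthetic
qGY-psr-2D.1	GY	2008	0.59	C	synthetic
qGY-psr-2D.1	PH	MET	4.92	C	paper
qGY-psr-2D.1	PH	2005	6.42	C	synthetic
qGY-psr-2D.1	PH	2006	3.92	C	synthetic
qGY-psr-2D.1	PH	2007	2.92	C	synthetic
qGY-psr-2D.1	PH	2008	6.42	C	synthetic
qGY-psr-3A.2	GY	MET	0.16	C	synthetic
qGY-psr-3A.2	GY	2005	0.19	C	synthetic
qGY-psr-3A.2	GY	2006	0.04	C	synthetic
qGY-psr-3A.2	GY	2007	0.20	C	synthetic
qGY-psr-3A.2	GY	2008	0.21	C	synthetic
qGY-psr-3B.2	GY	MET	0.12	A	synthetic
qGY-psr-3B.2	GY	2005	0.14	A	synthetic
qGY-psr-3B.2	GY	2006	0.06	A	synthetic
qGY-psr-3B.2	GY	2007	0.13	A	synthetic
qGY-psr-3B.2	GY	2008	0.15	A	synthetic
qPH-psr-2A.1	GY	MET	0.21	A	paper
qPH-psr-2A.1	GY	2005	0.23	A	synthetic
qPH-psr-2A.1	GY	2006	0.13	A	synthetic
qPH-psr-2A.1	GY	2007	0.23	A	synthetic
qPH-psr-2A.1	GY	2008	0.25	A	synthetic
qPH-psr-2A.1	PH	MET	2.20	A	synthetic
qPH-psr-2A.1	PH	2005	2.60	A	synthetic
qPH-psr-2A.1	PH	2006	1.60	A	synthetic
qPH-psr-2A.1	PH	2007	2.30	A	synthetic
qPH-psr-2A.1	PH	2008	2.30	A	synthetic
qPH-psr-3A	PH	MET	4.42	C	paper
qPH-psr-3A	PH	2005	3.22	C	synthetic
qPH-psr-3A	PH	2006	5.22	C	synthetic
qPH-psr-3A	PH	2007	5.42	C	synthetic
qPH-psr-3A	PH	2008	3.82	C	synthetic
qPH-psr-3A	EM	MET	1.50	C	synthetic
qPH-psr-3A	EM	2005	1.10	C	synthetic
qPH-psr-3A	EM	2006	2.10	C	synthetic
qPH-psr-3A	EM	2007	1.40	C	synthetic
qPH-psr-3A	EM	2008	1.40	C	synthetic
qPH-psr-3B.1	PH	MET	2.40	A	paper
qPH-psr-3B.1	PH	2005	2.10	A	synthetic
qPH-psr-3B.1	PH	2006	2.90	A	synthetic
qPH-psr-3B.1	PH	2007	2.00	A	synthetic
qPH-psr-3B.1	PH	2008	2.60	A	synthetic
qPH-psr-4D	PH	MET	4.65	C	synthetic
qPH-psr-4D	PH	2005	5.55	C	synthetic
qPH-psr-4D	PH	2006	4.95	C	synthetic
qPH-psr-4D	PH	2007	3.85	C	synthetic
qPH-psr-4D	PH	2008	4.25	C	synthetic
qPH-psr-5A.1	PH	MET	1.80	C	synthetic
qPH-psr-5A.1	PH	2005	2.40	C	synthetic
qPH-psr-5A.1	PH	2006	1.60	C	synthetic
qPH-psr-5A.1	PH	2007	1.50	C	synthetic
qPH-psr-5A.1	PH	2008	1.70	C	synthetic
qEM-psr-1B.2	EM	MET	1.20	C	synthetic
qEM-psr-1B.2	EM	2005	1.50	C	synthetic
qEM-psr-1B.2	EM	2006	0.70	C	synthetic
qEM-psr-1B.2	EM	2007	1.30	C	synthetic
qEM-psr-1B.2	EM	2008	1.30	C	synthetic
qEM-psr-1D.1	EM	MET	2.40	A	synthetic
qEM-psr-1D.1	EM	2005	3.20	A	synthetic
qEM-psr-1D.1	EM	2006	2.00	A	synthetic
qEM-psr-1D.1	EM	2007	1.80	A	synthetic
qEM-psr-1D.1	EM	2008	2.60	A	synthetic
qEM-psr-5A	EM	MET	1.80	A	synthetic
qEM-psr-5A	EM	2005	2.30	A	synthetic
qEM-psr-5A	EM	2006	1.90	A	synthetic
qEM-psr-5A	EM	2007	1.40	A	synthetic
qEM-psr-5A	EM	2008	1.60	A	synthetic
qEM-psr-6A.1	EM	MET	1.00	C	synthetic
qEM-psr-6A.1	EM	2005	0.80	C	synthetic
qEM-psr-6A.1	EM	2006	1.30	C	synthetic
qEM-psr-6A.1	EM	2007	1.10	C	synthetic
qEM-psr-6A.1	EM	2008	0.80	C	synthetic
qTGW-psr-5A.1	TGW	MET	1.72	C	paper
qGRL-psr-5A.1	GRL	MET	0.15	C	paper
qGRW-psr-5A.2	GRW	MET	0.04	A	synthetic
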