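property	AA	AC	AG	AT	CA	CC	CG	CT	GA	GC	GG	GT	TA	TC	TG	TT
twist	35.8	33.9	33.4	31.2	36.9	33.0	35.4	33.4	37.4	36.1	33.0	33.9	39.1	37.4	36.9	35.8
tilt	-1.4	-0.1	-1.7	0.0	0.5	-0.1	0.0	1.7	-1.5	0.0	0.1	0.1	0.0	1.5	-0.5	1.4
roll	0.7	0.7	4.5	1.1	4.7	3.6	5.4	4.5	1.9	0.3	3.6	0.7	3.3	1.9	4.7	0.7
shift	-0.03	0.13	0.09	0.0	0.09	0.05	0.0	-0.09	-0.28	0.0	-0.05	-0.13	0.0	0.28	-0.09	0.03
slide	-0.08	-0.58	-0.25	-0.59	0.53	-0.22	0.41	-0.25	0.09	-0.38	-0.22	-0.58	0.05	0.09	0.53	-0.08
rise	3.27	3.36	3.34	3.31	3.33	3.42	3.39	3.34	3.37	3.40	3.42	3.36	3.42	3.37	3.33	3.27
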