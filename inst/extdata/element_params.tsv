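element	radius	lj_eps	asp	asp_charged
C	1.70	0.14	0.005	0.005
N	1.55	0.10	-0.002	-0.015
O	1.52	0.10	-0.002	-0.008
S	1.80	0.18	0.006	0.006
P	1.80	0.16	-0.002	-0.008
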