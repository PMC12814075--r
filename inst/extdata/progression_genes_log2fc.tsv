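gene	lfc_mid_vs_early	lfc_end_vs_mid	q_mid_vs_early	q_end_vs_mid
Aldoa	0.34	0.29	0.01	0.01
Anp32b	0.27	0.38	0.01	0.01
Aprt	0.27	0.32	0.01	0.01
Arl4a	0.31	0.25	0.01	0.01
Atf5	0.33	0.28	0.01	0.01
Capza2	0.79	2.53	0.01	0.01
Cct5	0.39	0.32	0.01	0.01
Cdkn2a	0.98	0.34	0.01	0.01
Eef1a1	0.48	0.47	0.01	0.01
Eef1b2	0.45	0.27	0.01	0.01
Eif3e	0.27	0.33	0.01	0.01
Eif5a	0.30	0.28	0.01	0.01
Fkbp3	0.28	0.32	0.01	0.01
H2afz	0.58	0.43	0.01	0.01
Igfbp2	0.36	0.40	0.01	0.01
Iigp1	0.71	0.36	0.01	0.01
Lgals1	0.42	0.90	0.01	0.01
Lmo4	0.29	0.27	0.01	0.01
Met	0.92	1.62	0.01	0.01
Mif	0.34	0.33	0.01	0.01
Moxd1	0.29	0.42	0.01	0.01
Noct	0.32	0.37	0.01	0.01
Npm1	0.30	0.46	0.01	0.01
Pebp1	0.35	0.29	0.01	0.01
Phlda1	0.27	0.44	0.01	0.01
Rpl19	0.31	0.26	0.01	0.01
Rpl30	0.40	0.30	0.01	0.01
Rpl37	0.29	0.30	0.01	0.01
Rpl8	0.42	0.44	0.01	0.01
Rps12	0.44	0.33	0.01	0.01
Rps3	0.58	0.26	0.01	0.01
Rps4x	0.57	0.28	0.01	0.01
Rps9	0.44	0.34	0.01	0.01
S100a10	0.52	0.27	0.01	0.01
Timp1	0.31	0.29	0.01	0.01
Tpm1	0.28	0.54	0.01	0.01
Tshz2	0.40	0.36	0.01	0.01
Tubb5	0.44	0.31	0.01	0.01
Ube2c	0.40	0.52	0.01	0.01
Ube2s	0.37	0.31	0.01	0.01
Uchl1	0.34	0.69	0.01	0.01
Vim	0.93	0.29	0.01	0.01
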