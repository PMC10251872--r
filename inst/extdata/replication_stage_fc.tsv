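pathway	fc_stage1	fc_lo_stage1	fc_hi_stage1	fc_stage2	fc_lo_stage2	fc_hi_stage2	fc_stage3	fc_lo_stage3	fc_hi_stage3	interaction_p
Nitrogen metabolism	-1.72	-1.94	-1.53	-1.76	-1.92	-1.61	-1.66	-1.79	-1.55	0.558
Proximal tubule bicarbonate reclamation	-1.27	-1.34	-1.20	-1.38	-1.44	-1.32	-1.34	-1.38	-1.29	1.29e-3
Pentose and glucuronate interconversions	-1.21	-1.28	-1.15	-1.32	-1.37	-1.27	-1.24	-1.28	-1.20	0.084
Retinol metabolism	-1.20	-1.24	-1.16	-1.27	-1.30	-1.23	-1.19	-1.22	-1.17	8.33e-3
Sulfur metabolism	-1.20	-1.29	-1.12	-1.31	-1.39	-1.24	-1.30	-1.36	-1.24	3.65e-2
Synthesis and degradation of ketone bodies	-1.18	-1.28	-1.09	-1.26	-1.34	-1.19	-1.22	-1.28	-1.16	0.353
Mineral absorption	-1.17	-1.21	-1.14	-1.16	-1.19	-1.14	-1.17	-1.19	-1.15	1.10e-7
Drug metabolism-cytochrome P450	-1.14	-1.18	-1.10	-1.20	-1.23	-1.17	-1.20	-1.22	-1.17	9.76e-3
Ascorbate and aldarate metabolism	-1.13	-1.19	-1.06	-1.30	-1.35	-1.24	-1.21	-1.25	-1.17	9.02e-4
Steroid hormone biosynthesis	-1.13	-1.17	-1.09	-1.19	-1.22	-1.16	-1.16	-1.18	-1.13	0.119
Chemical carcinogenesis	-1.11	-1.14	-1.08	-1.17	-1.19	-1.15	-1.17	-1.19	-1.15	2.70e-4
Metabolism of xenobiotics by cytochrome P450	-1.10	-1.14	-1.07	-1.16	-1.19	-1.13	-1.15	-1.18	-1.13	8.91e-3
Bile secretion	-1.10	-1.13	-1.07	-1.14	-1.16	-1.12	-1.13	-1.15	-1.11	1.37e-2
Fatty acid degradation	-1.09	-1.13	-1.06	-1.21	-1.24	-1.18	-1.19	-1.21	-1.17	1.50e-7
Porphyrin and chlorophyll metabolism	-1.09	-1.13	-1.05	-1.17	-1.20	-1.13	-1.13	-1.16	-1.11	3.74e-2
Butanoate metabolism	-1.06	-1.10	-1.03	-1.14	-1.17	-1.11	-1.12	-1.15	-1.10	7.69e-3
Valine, leucine and isoleucine degradation	-1.05	-1.09	-1.02	-1.18	-1.20	-1.15	-1.14	-1.16	-1.12	4.24e-8
Tryptophan metabolism	-1.05	-1.08	-1.02	-1.08	-1.11	-1.06	-1.09	-1.11	-1.07	8.57e-3
Tyrosine metabolism	-1.05	-1.09	-1.01	-1.11	-1.14	-1.08	-1.09	-1.12	-1.07	0.139
Taste transduction	-1.05	-1.07	-1.04	-1.05	-1.06	-1.04	-1.05	-1.05	-1.04	0.453
Phototransduction	-1.04	-1.06	-1.02	-1.07	-1.09	-1.06	-1.06	-1.08	-1.05	3.09e-2
Ovarian steroidogenesis	-1.04	-1.06	-1.01	-1.03	-1.05	-1.01	-1.04	-1.05	-1.02	0.967
Cardiac muscle contraction	-1.03	-1.05	-1.02	-1.06	-1.07	-1.05	-1.05	-1.06	-1.04	4.24e-9
Pantothenate and CoA biosynthesis	-1.03	-1.07	1.00	-1.03	-1.06	-1.00	-1.03	-1.05	-1.01	1.18e-2
beta-Alanine metabolism	1.01	-1.02	1.04	-1.03	-1.05	-1.01	-1.03	-1.05	-1.01	4.25e-2
Folate biosynthesis	1.02	-1.01	1.06	-1.03	-1.06	-1.00	-1.01	-1.03	1.01	1.30e-3
Primary bile acid biosynthesis	1.08	1.03	1.14	-1.01	-1.05	1.02	-1.01	-1.04	1.02	1.66e-2
Riboflavin metabolism	1.09	1.02	1.17	-1.03	-1.08	1.02	1.01	-1.03	1.05	2.98e-3
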