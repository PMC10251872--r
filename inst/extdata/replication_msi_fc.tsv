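pathway	fc_MSI	fc_lo_MSI	fc_hi_MSI	fc_MSS	fc_lo_MSS	fc_hi_MSS	interaction_p
Nitrogen metabolism	-1.72	-1.89	-1.56	-1.70	-1.80	-1.60	0.232
Sulfur metabolism	-1.36	-1.44	-1.28	-1.26	-1.31	-1.21	2.03e-2
Proximal tubule bicarbonate reclamation	-1.36	-1.42	-1.30	-1.33	-1.37	-1.30	0.069
Pentose and glucuronate interconversions	-1.35	-1.40	-1.29	-1.23	-1.26	-1.20	3.37e-6
Synthesis and degradation of ketone bodies	-1.32	-1.41	-1.24	-1.19	-1.24	-1.15	4.83e-3
Ascorbate and aldarate metabolism	-1.29	-1.35	-1.23	-1.20	-1.23	-1.16	8.54e-7
Retinol metabolism	-1.27	-1.31	-1.23	-1.20	-1.22	-1.18	1.78e-4
Steroid hormone biosynthesis	-1.22	-1.25	-1.18	-1.14	-1.16	-1.12	1.80e-4
Drug metabolism-cytochrome P450	-1.22	-1.25	-1.19	-1.17	-1.19	-1.15	2.32e-4
Fatty acid degradation	-1.21	-1.23	-1.18	-1.17	-1.19	-1.15	5.42e-11
Chemical carcinogenesis	-1.18	-1.21	-1.16	-1.15	-1.16	-1.13	6.15e-5
Porphyrin and chlorophyll metabolism	-1.17	-1.21	-1.13	-1.12	-1.14	-1.10	4.22e-5
Metabolism of xenobiotics by cytochrome P450	-1.17	-1.20	-1.14	-1.14	-1.15	-1.12	1.78e-4
Bile secretion	-1.16	-1.18	-1.13	-1.12	-1.14	-1.11	3.57e-2
Valine, leucine and isoleucine degradation	-1.15	-1.18	-1.12	-1.13	-1.14	-1.11	1.96e-16
Mineral absorption	-1.15	-1.18	-1.12	-1.17	-1.19	-1.15	0.193
Butanoate metabolism	-1.14	-1.17	-1.11	-1.11	-1.13	-1.09	1.17e-4
Tyrosine metabolism	-1.11	-1.14	-1.08	-1.08	-1.10	-1.06	0.198
Phototransduction	-1.08	-1.10	-1.06	-1.06	-1.07	-1.05	0.100
Tryptophan metabolism	-1.07	-1.10	-1.05	-1.08	-1.09	-1.06	1.74e-5
Cardiac muscle contraction	-1.05	-1.06	-1.04	-1.05	-1.05	-1.04	1.00e-5
Folate biosynthesis	-1.04	-1.07	-1.01	1.00	-1.02	1.02	9.67e-3
Riboflavin metabolism	-1.04	-1.10	1.02	1.03	-1.01	1.06	0.079
Taste transduction	-1.04	-1.06	-1.03	-1.05	-1.06	-1.04	0.366
Ovarian steroidogenesis	-1.04	-1.06	-1.02	-1.04	-1.05	-1.02	0.930
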