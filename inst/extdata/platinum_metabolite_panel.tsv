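metabolite	carboplatin_r	carboplatin_sig	cisplatin_r	cisplatin_sig	iproplatin_r	iproplatin_sig	tetraplatin_r	tetraplatin_sig	diaminocyclohexyl_Pt_II_r	diaminocyclohexyl_Pt_II_sig
2-oxoglutarate	0.18	FALSE	0.26	TRUE	0.20	FALSE	0.12	FALSE	0.16	TRUE
Adenine	0.01	FALSE	-0.01	FALSE	0.13	FALSE	0.21	TRUE	0.15	TRUE
beta-alanine	-0.13	FALSE	-0.04	FALSE	0.05	FALSE	0.28	TRUE	0.23	TRUE
Citrate	0.00	FALSE	0.01	FALSE	0.23	FALSE	0.21	TRUE	0.19	TRUE
CMP	-0.04	FALSE	-0.04	FALSE	0.15	FALSE	0.22	TRUE	0.21	TRUE
dUTP	0.20	FALSE	0.25	TRUE	0.20	FALSE	0.24	TRUE	0.25	TRUE
L-glutamate	0.00	FALSE	0.09	FALSE	0.02	FALSE	0.23	TRUE	0.22	TRUE
Phosphoenolpyruvate	0.00	FALSE	0.09	FALSE	0.26	TRUE	0.33	TRUE	0.30	TRUE
S-adenosyl-L-methionine	0.02	FALSE	-0.01	FALSE	0.20	FALSE	0.27	TRUE	0.20	TRUE
Taurine	-0.14	FALSE	-0.03	FALSE	0.11	FALSE	0.45	TRUE	0.35	TRUE
Cholesterol	-0.16	FALSE	-0.25	TRUE	-0.35	TRUE	-0.37	TRUE	-0.38	TRUE
Deoxyuridine	0.03	FALSE	0.02	FALSE	-0.02	FALSE	-0.21	TRUE	-0.18	TRUE
Glycerol	-0.21	FALSE	-0.27	TRUE	-0.43	TRUE	-0.38	TRUE	-0.36	TRUE
Guanine	-0.02	FALSE	-0.04	FALSE	-0.15	FALSE	-0.20	TRUE	-0.18	TRUE
Guanosine	-0.06	FALSE	-0.16	FALSE	-0.30	TRUE	-0.24	TRUE	-0.30	TRUE
Hexadecanoic acid	0.03	FALSE	-0.09	FALSE	-0.26	TRUE	-0.22	TRUE	-0.27	TRUE
Hypoxanthine	-0.36	TRUE	-0.36	TRUE	-0.13	FALSE	-0.05	FALSE	-0.04	FALSE
Inosine	-0.21	FALSE	-0.25	TRUE	-0.07	FALSE	-0.05	FALSE	-0.10	FALSE
Uracil	-0.19	FALSE	-0.25	TRUE	-0.28	TRUE	-0.19	TRUE	-0.21	TRUE
Urea	-0.14	FALSE	-0.25	TRUE	-0.31	TRUE	-0.36	TRUE	-0.37	TRUE
Uridine	-0.38	TRUE	-0.34	TRUE	-0.17	FALSE	-0.18	TRUE	-0.20	TRUE
Xanthine	-0.32	TRUE	-0.25	TRUE	-0.13	FALSE	-0.07	FALSE	-0.02	FALSE
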