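# Hydrocarbon screening panel: 39 hydrocarbons plus pentane solvent control
# (solvent is not a row; it is panel metadata). Screen dose 20 nmol per
# cartridge. on_cuticle marks the 17 panel members reported from
# H. saltator cuticular extracts; flags are a TRANSCRIPTION from figure
# label colouring in the source screen, not a machine-readable original.
# methyl_positions: comma-joined carbon positions, empty for none.
# double_bond_position/geometry: empty unless hc_class == alkene.
name	chain_length	hc_class	methyl_positions	double_bond_position	double_bond_geometry	on_cuticle
C10	10	n-alkane				FALSE
C11	11	n-alkane				FALSE
C12	12	n-alkane				FALSE
C13	13	n-alkane				FALSE
C14	14	n-alkane				FALSE
C15	15	n-alkane				FALSE
C16	16	n-alkane				FALSE
C17	17	n-alkane				FALSE
C18	18	n-alkane				FALSE
C20	20	n-alkane				FALSE
C21	21	n-alkane				FALSE
C22	22	n-alkane				FALSE
C23	23	n-alkane				FALSE
C24	24	n-alkane				FALSE
C25	25	n-alkane				FALSE
C26	26	n-alkane				FALSE
C27	27	n-alkane				TRUE
C28	28	n-alkane				TRUE
C29	29	n-alkane				TRUE
C30	30	n-alkane				TRUE
C31	31	n-alkane				TRUE
C32	32	n-alkane				TRUE
C33	33	n-alkane				TRUE
C34	34	n-alkane				TRUE
C35	35	n-alkane				TRUE
Z9-C29:1	29	alkene		9	Z	TRUE
Z9-C31:1	31	alkene		9	Z	TRUE
2-MeC28	28	monomethyl	2			FALSE
3-MeC29	29	monomethyl	3			FALSE
13-MeC29	29	monomethyl	13			TRUE
5-MeC31	31	monomethyl	5			TRUE
13-MeC31	31	monomethyl	13			TRUE
15-MeC31	31	monomethyl	15			TRUE
13-MeC33	33	monomethyl	13			FALSE
15-MeC33	33	monomethyl	15			FALSE
3,11-DiMeC29	29	dimethyl	3,11			FALSE
5,17-DiMeC29	29	dimethyl	5,17			FALSE
13,23-DiMeC35	35	dimethyl	13,23			TRUE
13,23-DiMeC37	37	dimethyl	13,23			TRUE
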