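# HIS0-protein interaction inputs per interaction type and residue.
# Energies follow published ab initio estimates for histidine-amino-acid
# interaction pairs; hp follows the Black & Mould (1991) hydrophobicity
# scale, shifted so glycine is 0; SAA columns are MD ensemble averages for
# an IgG-class antibody's Fc and Fab fragments and Ala-X-Ala references.
# energy_kcal_mol: pairwise interaction energy (cation_pi, pi_pi, h_pi rows);
# hp: Black & Mould hydrophobicity, glycine-shifted (h_bond rows);
# saa_*_avg_nm2: trajectory-averaged residue-type SAA on the Fc / Fab fragment;
# saa_exposed_nm2: fully-exposed Ala-X-Ala side-chain SAA. All areas in nm^2.
interaction_type	residue_name	energy_kcal_mol	hp	saa_fc_avg_nm2	saa_fab_avg_nm2	saa_exposed_nm2
cation_pi	ARG	-8.193	NA	12.9	12.5	2.22
cation_pi	LYS	-9.268	NA	34.5	28.3	1.93
pi_pi	PHE	-0.093	NA	4.7	2.5	1.9
pi_pi	TYR	-0.098	NA	9.4	9.5	2.0
pi_pi	TRP	-0.535	NA	0.7	0.3	2.3
pi_pi	ARG	-2.402	NA	12.9	12.3	2.2
h_pi	PHE	-2.735	NA	4.7	2.5	1.9
h_pi	TYR	-2.599	NA	9.4	9.5	2.0
h_pi	TRP	-3.679	NA	0.7	0.3	2.3
h_bond	ARG	NA	-0.50	12.9	12.5	2.2
h_bond	ASN	NA	-0.27	17.7	8.4	1.4
h_bond	ASP	NA	-0.47	9.9	8.2	1.2
h_bond	GLN	NA	-0.25	17.6	11.2	1.6
h_bond	GLU	NA	-0.46	20.2	9.7	1.5
h_bond	LYS	NA	-0.22	34.5	28.3	1.9
h_bond	SER	NA	-0.14	13.9	34.9	1.0
h_bond	THR	NA	-0.05	9.7	19.3	1.2
h_bond	HIS	NA	-0.34	9.7	2.1	1.6
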