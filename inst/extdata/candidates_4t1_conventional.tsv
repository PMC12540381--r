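neoantigen_id	cross_id	synthesis_failed	hla_allele	allele_frequency	amino_acid_change	gene_symbol	peptide_position	mut_mhc_ic50	priority_score	augmented_peptide
C1	NA	FALSE	H-2-Dd	1	P/L	Dtx2	8	1654.6	100	CLSRAPRPTGPPASRLASKSHSSVKRLRKMS
C2	NA	FALSE	H2-Ld	1	E/G	Sh3d21	6	12906.2	98	IPATEDTTLDKAGTPGSTLSGNKPAKDEALD
C3	M6	FALSE	H-2-Kd	0.778	R/W	Icmt	2	9856.8	77	MAGCAAWVPPGSEARLSLATFLLGASVLALP
C4	NA	FALSE	H2-Ld	1	R/L	Dhx58	9	7777.9	75	LLETPRGKIQAKKWSLVPFSIPVFDILQDCT
C5	NA	FALSE	H-2-Kd	0.738	M/I	Polr2a	9	8697.4	56	VGALAAQSLGEPATQITLNTFHYAGVSAKNV
C6	M7	FALSE	H-2-Dd	0.563	C/G	Scrn1	2	13181.7	55	AWLWGAEMGANEHGVGIANEAINAREPAAET
C7	M8	FALSE	H2-Ld	0.581	R/P	Lancl3	2	9614.6	54	LQMLLSYQEHLKPSDPELVWQSVDFLMEQEQ
C8	M5	FALSE	H-2-Kd	0.502	K/T	Zfr	7	4033.6	49	AYAAHIRGAKHQKVVTLHTKLGKPIPSTEPN
C9	NA	FALSE	H-2-Kd	0.465	H/Y	Wdr33	2	760.3	46	MATEIGSPPRFFYMPRFQHQAPRQLFYKRPD
C10	NA	TRUE	H2-Ld	0.562	D/G	Chd2	6	8635.9	43	RKPRVKKENKAPRLKGEHGLEPASPRHSDNP
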