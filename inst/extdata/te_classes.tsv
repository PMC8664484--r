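class	group	elements	sequence_length_bp	genome_pct
LTR/Gypsy	interspersed	853285	1333833165	33.17
LTR/Copia	interspersed	383555	644052368	16.02
LTR/Unknown	interspersed	456559	611381110	15.20
Non-LTR/LINE	interspersed	192648	80369034	2.00
Non-LTR/SINE	interspersed	19503	3344990	0.08
CACTA	interspersed	201749	203285995	5.05
Mutator	interspersed	29706	10397597	0.26
PIF-Harbinger	interspersed	77072	22128071	0.55
Tc1-Mariner	interspersed	166095	48513995	1.20
hAT	interspersed	17127	3870055	0.09
Helitron	interspersed	219796	113044338	2.81
MITE/Stowaway	interspersed	1139	174827	0.00
MITE/Tourist	interspersed	453	80546	0.00
DNA/unknown	interspersed	1245	296555	0.01
Unspecified	interspersed	393632	410074883	10.20
Total interspersed	subtotal	3013564	3484847529	86.65
Low complexity	other	20328	1104950	0.03
Simple repeat	other	173933	7922189	0.20
Total	grand	3207825	3493874668	86.88
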