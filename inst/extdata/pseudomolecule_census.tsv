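pseudomolecule	version	total_length	gap_length	effective_length	gap_number
Chr1	v4.0	502330251	10377979	491952272	11744
Chr1	v5.0	501967303	8406331	493560972	6647
Chr2	v4.0	651661114	10780418	640880696	14522
Chr2	v5.0	650458083	8558830	641899253	8139
Chr3	v4.0	627182665	11118990	616063675	14404
Chr3	v5.0	627456150	9202775	618253375	9437
Chr4	v4.0	526018785	9454858	516563927	10892
Chr4	v5.0	525206139	8086205	517119934	6175
Chr5	v4.0	577375663	14628972	562746691	13506
Chr5	v5.0	576238907	12629354	563609553	7615
Chr6	v4.0	496019527	9112991	486906536	11357
Chr6	v5.0	495363004	7581178	487781826	6199
Chr7	v4.0	644716137	17324389	627391748	15384
Chr7	v5.0	644841383	14867162	629974221	8698
Total	v4.0	4025304142	82798597	3942505545	91809
Total	v5.0	4021530969	69331835	3952199134	52910
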