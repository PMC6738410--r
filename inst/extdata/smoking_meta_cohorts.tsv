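# published per-cohort smoking association statistics, seven validation cohorts
# t_dnamtl / t_ltl: t statistics of the smoking term for the methylation-based
# and the measured telomere-length outcome respectively
cohort	n	variable	t_dnamtl	t_ltl
FHS	878	Pack years	-2.08	0.54
WHI_BA23	97	Pack years	0.45	1.30
JHS	100	Smoker	-3.00	-1.87
LBC_1921	404	Pack years	-3.53	-0.92
LBC_1936	796	Pack years	-3.55	0.55
UK_Twin	792	Smoker	-2.79	-3.23
BHS	831	Smoker	-6.83	-1.83
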