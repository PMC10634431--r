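species	symbol	feature	sequence
homosapiens	TRBV6-4	CDR1-IMGT	MRHNA
homosapiens	TRBV6-4	CDR2-IMGT	SNTAGT
homosapiens	TRBV6-4	FR3-IMGT	DKGEVPNGYNVSRLKKQNFLLGLESAAPSQTSVYF
homosapiens	TRBV5-1	CDR1-IMGT	SGHRS
homosapiens	TRBV5-1	CDR2-IMGT	YFSETQ
homosapiens	TRBV19	CDR1-IMGT	LNHDA
homosapiens	TRBV19	CDR2-IMGT	SQIVND
homosapiens	TRAJ1	FR4-IMGT	GFGTRLSVIA
musmusculus	TRBV2	CDR1-IMGT	NSQYPW
musmusculus	TRBV2	CDR2-IMGT	LRSPGD
musmusculus	TRAV14D-3/DV8	CDR1-IMGT	TSSLSN
musmusculus	TRAV14D-3/DV8	CDR2-IMGT	LVKSGE
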