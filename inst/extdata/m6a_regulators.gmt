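readers	reader	YTHDF1	YTHDF2	YTHDF3	YTHDC1	YTHDC2	IGF2BP1	HNRNPA2B1	HNRNPC	FMR1	LRPPRC	ELAVL1
writers	writer	METTL3	METTL14	WTAP	RBM15	RBM15B	ZC3H13	CBLL1
erasers	eraser	ALKBH5	FTO
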