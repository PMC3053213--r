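probe_id	gene_symbol	pattern
202502_at	ACADM	Consistent (ISR > No-ISR)
221504_s_at	ATP6V1H	Consistent (ISR > No-ISR)
202654_x_at	AXOT	Consistent (ISR > No-ISR)
212460_at	C14orf147	Divergent (ISR > No-ISR)
203994_s_at	C21orf2	Consistent (No-ISR > ISR)
203996_s_at	C21orf2	Consistent (No-ISR > ISR)
208374_s_at	CAPZA1	Consistent (ISR > No-ISR)
217886_at	EPS15	Consistent (ISR > No-ISR)
218646_at	FLJ20534	Consistent (ISR > No-ISR)
204829_s_at	FOLR2	Consistent (ISR > No-ISR)
220131_at	FXYD7	Consistent (No-ISR > ISR)
217814_at	GK001	Consistent (ISR > No-ISR)
218092_s_at	HRB	Consistent (ISR > No-ISR)
212411_at	IMP4	Divergent (No-ISR > ISR)
200821_at	LAMP2	Consistent (ISR > No-ISR)
203276_at	LMNB1	Consistent (ISR > No-ISR)
214773_x_at	MGC3794	Consistent (ISR > No-ISR)
212803_at	NAB2	Consistent (No-ISR > ISR)
203371_s_at	NDUFB3	Consistent (ISR > No-ISR)
218047_at	OSBPL9	Consistent (ISR > No-ISR)
221123_x_at	PBF	Consistent (No-ISR > ISR)
208857_s_at	PCMT1	Consistent (ISR > No-ISR)
205202_at	PCMT1	Consistent (ISR > No-ISR)
209345_s_at	PI4KII	Consistent (No-ISR > ISR)
201222_s_at	RAD23B	Divergent (ISR > No-ISR)
201223_s_at	RAD23B	Consistent (ISR > No-ISR)
209207_s_at	SEC22L1	Consistent (ISR > No-ISR)
217758_s_at	SMBP	Consistent (ISR > No-ISR)
203605_at	SRP54	Consistent (ISR > No-ISR)
212513_s_at	USP33	Consistent (ISR > No-ISR)
201807_at	VPS26	Consistent (ISR > No-ISR)
210849_s_at	VPS41	Divergent (ISR > No-ISR)
205126_at	VRK2	Divergent (ISR > No-ISR)
216304_x_at	YME1L1	Consistent (ISR > No-ISR)
201351_s_at	YME1L1	Consistent (ISR > No-ISR)
222294_s_at	RAB27A	Consistent (ISR > No-ISR)
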