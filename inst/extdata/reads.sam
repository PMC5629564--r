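@HD	VN:1.6	SO:coordinate
@SQ	SN:chr1	LN:10000
r1	0	chr1	1010	60	40M	*	0	0	AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA	*
r5	0	chr1	1181	60	40M	*	0	0	AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA	*
r6	0	chr1	1231	60	40M	*	0	0	AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA	*
r2	0	chr1	1660	60	40M	*	0	0	AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA	*
r7	0	chr1	2051	60	40M	*	0	0	AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA	*
r8	0	chr1	2251	60	40M	*	0	0	AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA	*
r4	0	chr1	2601	60	40M	*	0	0	AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA	*
r3	4	*	0	0	*	*	0	0	AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA	*
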