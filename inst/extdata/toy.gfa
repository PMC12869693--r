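H	VN:Z:1.0
S	s1	GATTA
S	s2	C
S	s3	T
S	s4	AGGA
S	s5	TC
S	s6	T
S	s7	CCAGT
S	s8	TGA
L	s1	+	s2	+	0M
L	s1	+	s3	+	0M
L	s2	+	s4	+	0M
L	s3	+	s4	+	0M
L	s4	+	s5	+	0M
L	s4	+	s6	+	0M
L	s5	+	s7	+	0M
L	s6	+	s7	+	0M
L	s7	+	s8	+	0M
P	hap1	s1+,s2+,s4+,s5+,s7+,s8+	*
P	hap2	s1+,s3+,s4+,s6+,s7+,s8+	*
P	hap3	s1+,s2+,s4+,s6+,s7+,s8+	*
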