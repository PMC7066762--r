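H	VN:Z:1.0
S	n1	TC
S	n2	G
S	n3	T
S	n4	CA
S	n5	A
S	n6	C
S	n7	GG
L	n1	+	n2	+	0M
L	n1	+	n3	+	0M
L	n2	+	n4	+	0M
L	n3	+	n4	+	0M
L	n4	+	n5	+	0M
L	n4	+	n6	+	0M
L	n5	+	n7	+	0M
L	n6	+	n7	+	0M
P	I	n1+,n2+,n4+,n5+,n7+	*
P	II	n1+,n2+,n4+,n6+,n7+	*
P	III	n1+,n3+,n4+,n6+,n7+	*
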