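upstream	downstream	direction	rank
APr	A3	up	11
APr	A3	up	19
APr	A3	up	26
APr	A3	up	27
APr	A3	up	28
APr	A3	up	30
APr	A3	down	2
APr	A3	down	3
APr	A3	down	8
APr	R	up	7
APr	R	up	10
APr	R	up	11
APr	R	up	14
APr	R	up	21
APr	R	up	22
APr	R	up	24
APr	R	up	30
APr	R	up	31
APr	R	up	32
APr	R	up	33
APr	R	down	3
APr	R	down	5
APr	R	down	8
APr	S	up	7
APr	S	up	33
APr	S	up	42
APr	S	down	5
A3	R	up	1
A3	R	up	4
A3	R	down	5
A3	S	up	2
A3	S	down	3
A5	A3	up	11
A5	A3	up	14
A5	A3	up	28
A5	A3	up	30
A5	A3	up	34
A5	A3	up	42
A5	A3	down	2
A5	A3	down	3
A5	A3	down	5
A5	A3	down	7
A5	A3	down	8
A5	A3	down	10
A5	A5	up	4
A5	A5	up	33
A5	A5	down	3
A5	R	up	6
A5	R	up	10
A5	R	up	11
A5	R	up	14
A5	R	up	15
A5	R	up	19
A5	R	up	22
A5	R	up	25
A5	R	up	26
A5	R	up	27
A5	R	up	28
A5	R	up	30
A5	R	up	31
A5	R	up	32
A5	R	up	33
A5	R	up	34
A5	R	down	1
A5	R	down	2
A5	R	down	3
A5	R	down	9
A5	S	up	11
A5	S	up	12
A5	S	up	41
A5	S	up	42
A5	S	down	1
A5	S	down	8
ME	R	down	1
R	A3	up	1
R	A3	up	4
R	A3	up	32
R	A3	down	5
R	A3	down	8
R	A3	down	11
R	A3	down	12
R	A3	down	17
R	R	up	2
R	R	up	3
R	R	up	4
R	R	up	8
R	R	up	9
R	R	up	29
R	R	up	37
R	R	down	7
R	R	down	11
R	R	down	16
R	R	down	19
R	R	down	21
R	R	down	22
R	R	down	24
R	R	down	26
R	R	down	27
R	R	down	30
R	R	down	31
R	R	down	32
R	R	down	33
R	R	down	34
R	R	down	42
R	S	up	1
R	S	up	3
R	S	up	42
R	S	down	11
R	APA	up	1
R	APA	up	7
R	APA	down	4
S	A5	up	13
S	R	up	6
S	R	up	11
S	R	up	20
S	R	up	22
S	R	up	41
S	R	down	1
S	R	down	4
S	S	up	3
S	S	up	5
S	S	up	13
S	S	up	17
S	S	up	18
S	S	down	4
S	S	down	10
S	S	down	14
S	S	down	31
S	APA	up	3
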