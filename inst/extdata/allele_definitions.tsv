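gene	allele	function_class	activity_value
CYP2C19	*1	normal	NA
CYP2C19	*2	no_function	NA
CYP2C19	*3	no_function	NA
CYP2C19	*4	no_function	NA
CYP2C19	*5	no_function	NA
CYP2C19	*6	no_function	NA
CYP2C19	*7	no_function	NA
CYP2C19	*8	no_function	NA
CYP2C19	*9	decreased	NA
CYP2C19	*10	decreased	NA
CYP2C19	*12	uncertain	NA
CYP2C19	*17	increased	NA
CYP2D6	*1	normal	1.0
CYP2D6	*2	normal	1.0
CYP2D6	*33	normal	1.0
CYP2D6	*35	normal	1.0
CYP2D6	*3	no_function	0
CYP2D6	*4	no_function	0
CYP2D6	*5	no_function	0
CYP2D6	*6	no_function	0
CYP2D6	*7	no_function	0
CYP2D6	*8	no_function	0
CYP2D6	*36	no_function	0
CYP2D6	*40	no_function	0
CYP2D6	*56	no_function	0
CYP2D6	*9	decreased	0.5
CYP2D6	*17	decreased	0.5
CYP2D6	*29	decreased	0.5
CYP2D6	*10	decreased	0.25
CYP2D6	*41	decreased	0.25
CYP2D6	*22	uncertain	NA
CYP2D6	*36+*10	decreased	0.25
CYP2D6	*68+*4	no_function	0
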