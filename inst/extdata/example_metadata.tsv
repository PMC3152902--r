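strain_id	group	panel_id	is_outgroup
A_1	A	panel1	FALSE
A_2	A	panel1	FALSE
B1_1	B1	panel1	FALSE
B1_2	B1	panel1	FALSE
B2_1	B2	panel1	FALSE
B2_2	B2	panel1	FALSE
OUTGROUP	O	panel1	TRUE
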