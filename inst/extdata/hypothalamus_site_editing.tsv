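# Reference hypothalamic per-site editing percentages (edited reads /
# tallied reads * 100) for lean control and ob/ob groups.
site	pct_lean	pct_obob
A	87.58	90.01
B	75.23	76.67
E	3.67	3.01
C	24.39	23.7
D	55.18	50.65
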