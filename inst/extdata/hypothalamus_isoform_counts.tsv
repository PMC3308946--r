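# Reference hypothalamic pyrosequencing isoform counts:
# classified editing-cassette reads per isoform for lean control and
# leptin-deficient ob/ob mice (grand total 20951).
edited_sites	count_lean	count_obob
ABD	3607	3429
AD	283	253
AB	1871	2175
A	857	962
ABCD	1278	1094
ACD	60	63
-	720	588
ABECD	37	25
AECD	11	6
ABC	850	997
AC	119	114
B	45	48
E	19	12
C	67	61
D	354	203
ABED	98	77
AED	16	9
ABE	84	70
AE	26	24
CD	30	52
BD	54	41
ABEC	30	29
AEC	31	21
ECD	1	10
BC	6	9
EC	6	2
ED	14	3
BE	0	0
BEC	0	0
BED	0	0
BCD	0	0
BECD	0	0
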