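type	position	guide_base	off_base	pam2	penalty
mismatch	1	A	C	NA	0.85
mismatch	1	A	G	NA	0.9175
mismatch	1	A	T	NA	0.85
mismatch	1	C	A	NA	0.85
mismatch	1	C	G	NA	0.85
mismatch	1	C	T	NA	0.9175
mismatch	1	G	A	NA	0.955
mismatch	1	G	C	NA	0.85
mismatch	1	G	T	NA	0.85
mismatch	1	T	A	NA	0.85
mismatch	1	T	C	NA	0.9175
mismatch	1	T	G	NA	0.85
mismatch	2	A	C	NA	0.8158
mismatch	2	A	G	NA	0.8987
mismatch	2	A	T	NA	0.8158
mismatch	2	C	A	NA	0.8158
mismatch	2	C	G	NA	0.8158
mismatch	2	C	T	NA	0.8987
mismatch	2	G	A	NA	0.9447
mismatch	2	G	C	NA	0.8158
mismatch	2	G	T	NA	0.8158
mismatch	2	T	A	NA	0.8158
mismatch	2	T	C	NA	0.8987
mismatch	2	T	G	NA	0.8158
mismatch	3	A	C	NA	0.7816
mismatch	3	A	G	NA	0.8799
mismatch	3	A	T	NA	0.7816
mismatch	3	C	A	NA	0.7816
mismatch	3	C	G	NA	0.7816
mismatch	3	C	T	NA	0.8799
mismatch	3	G	A	NA	0.9345
mismatch	3	G	C	NA	0.7816
mismatch	3	G	T	NA	0.7816
mismatch	3	T	A	NA	0.7816
mismatch	3	T	C	NA	0.8799
mismatch	3	T	G	NA	0.7816
mismatch	4	A	C	NA	0.7474
mismatch	4	A	G	NA	0.8611
mismatch	4	A	T	NA	0.7474
mismatch	4	C	A	NA	0.7474
mismatch	4	C	G	NA	0.7474
mismatch	4	C	T	NA	0.8611
mismatch	4	G	A	NA	0.9242
mismatch	4	G	C	NA	0.7474
mismatch	4	G	T	NA	0.7474
mismatch	4	T	A	NA	0.7474
mismatch	4	T	C	NA	0.8611
mismatch	4	T	G	NA	0.7474
mismatch	5	A	C	NA	0.7132
mismatch	5	A	G	NA	0.8422
mismatch	5	A	T	NA	0.7132
mismatch	5	C	A	NA	0.7132
mismatch	5	C	G	NA	0.7132
mismatch	5	C	T	NA	0.8422
mismatch	5	G	A	NA	0.9139
mismatch	5	G	C	NA	0.7132
mismatch	5	G	T	NA	0.7132
mismatch	5	T	A	NA	0.7132
mismatch	5	T	C	NA	0.8422
mismatch	5	T	G	NA	0.7132
mismatch	6	A	C	NA	0.6789
mismatch	6	A	G	NA	0.8234
mismatch	6	A	T	NA	0.6789
mismatch	6	C	A	NA	0.6789
mismatch	6	C	G	NA	0.6789
mismatch	6	C	T	NA	0.8234
mismatch	6	G	A	NA	0.9037
mismatch	6	G	C	NA	0.6789
mismatch	6	G	T	NA	0.6789
mismatch	6	T	A	NA	0.6789
mismatch	6	T	C	NA	0.8234
mismatch	6	T	G	NA	0.6789
mismatch	7	A	C	NA	0.6447
mismatch	7	A	G	NA	0.8046
mismatch	7	A	T	NA	0.6447
mismatch	7	C	A	NA	0.6447
mismatch	7	C	G	NA	0.6447
mismatch	7	C	T	NA	0.8046
mismatch	7	G	A	NA	0.8934
mismatch	7	G	C	NA	0.6447
mismatch	7	G	T	NA	0.6447
mismatch	7	T	A	NA	0.6447
mismatch	7	T	C	NA	0.8046
mismatch	7	T	G	NA	0.6447
mismatch	8	A	C	NA	0.6105
mismatch	8	A	G	NA	0.7858
mismatch	8	A	T	NA	0.6105
mismatch	8	C	A	NA	0.6105
mismatch	8	C	G	NA	0.6105
mismatch	8	C	T	NA	0.7858
mismatch	8	G	A	NA	0.8832
mismatch	8	G	C	NA	0.6105
mismatch	8	G	T	NA	0.6105
mismatch	8	T	A	NA	0.6105
mismatch	8	T	C	NA	0.7858
mismatch	8	T	G	NA	0.6105
mismatch	9	A	C	NA	0.5763
mismatch	9	A	G	NA	0.767
mismatch	9	A	T	NA	0.5763
mismatch	9	C	A	NA	0.5763
mismatch	9	C	G	NA	0.5763
mismatch	9	C	T	NA	0.767
mismatch	9	G	A	NA	0.8729
mismatch	9	G	C	NA	0.5763
mismatch	9	G	T	NA	0.5763
mismatch	9	T	A	NA	0.5763
mismatch	9	T	C	NA	0.767
mismatch	9	T	G	NA	0.5763
mismatch	10	A	C	NA	0.5421
mismatch	10	A	G	NA	0.7482
mismatch	10	A	T	NA	0.5421
mismatch	10	C	A	NA	0.5421
mismatch	10	C	G	NA	0.5421
mismatch	10	C	T	NA	0.7482
mismatch	10	G	A	NA	0.8626
mismatch	10	G	C	NA	0.5421
mismatch	10	G	T	NA	0.5421
mismatch	10	T	A	NA	0.5421
mismatch	10	T	C	NA	0.7482
mismatch	10	T	G	NA	0.5421
mismatch	11	A	C	NA	0.5079
mismatch	11	A	G	NA	0.7293
mismatch	11	A	T	NA	0.5079
mismatch	11	C	A	NA	0.5079
mismatch	11	C	G	NA	0.5079
mismatch	11	C	T	NA	0.7293
mismatch	11	G	A	NA	0.8524
mismatch	11	G	C	NA	0.5079
mismatch	11	G	T	NA	0.5079
mismatch	11	T	A	NA	0.5079
mismatch	11	T	C	NA	0.7293
mismatch	11	T	G	NA	0.5079
mismatch	12	A	C	NA	0.4737
mismatch	12	A	G	NA	0.7105
mismatch	12	A	T	NA	0.4737
mismatch	12	C	A	NA	0.4737
mismatch	12	C	G	NA	0.4737
mismatch	12	C	T	NA	0.7105
mismatch	12	G	A	NA	0.8421
mismatch	12	G	C	NA	0.4737
mismatch	12	G	T	NA	0.4737
mismatch	12	T	A	NA	0.4737
mismatch	12	T	C	NA	0.7105
mismatch	12	T	G	NA	0.4737
mismatch	13	A	C	NA	0.4395
mismatch	13	A	G	NA	0.6917
mismatch	13	A	T	NA	0.4395
mismatch	13	C	A	NA	0.4395
mismatch	13	C	G	NA	0.4395
mismatch	13	C	T	NA	0.6917
mismatch	13	G	A	NA	0.8318
mismatch	13	G	C	NA	0.4395
mismatch	13	G	T	NA	0.4395
mismatch	13	T	A	NA	0.4395
mismatch	13	T	C	NA	0.6917
mismatch	13	T	G	NA	0.4395
mismatch	14	A	C	NA	0.4053
mismatch	14	A	G	NA	0.6729
mismatch	14	A	T	NA	0.4053
mismatch	14	C	A	NA	0.4053
mismatch	14	C	G	NA	0.4053
mismatch	14	C	T	NA	0.6729
mismatch	14	G	A	NA	0.8216
mismatch	14	G	C	NA	0.4053
mismatch	14	G	T	NA	0.4053
mismatch	14	T	A	NA	0.4053
mismatch	14	T	C	NA	0.6729
mismatch	14	T	G	NA	0.4053
mismatch	15	A	C	NA	0.3711
mismatch	15	A	G	NA	0.6541
mismatch	15	A	T	NA	0.3711
mismatch	15	C	A	NA	0.3711
mismatch	15	C	G	NA	0.3711
mismatch	15	C	T	NA	0.6541
mismatch	15	G	A	NA	0.8113
mismatch	15	G	C	NA	0.3711
mismatch	15	G	T	NA	0.3711
mismatch	15	T	A	NA	0.3711
mismatch	15	T	C	NA	0.6541
mismatch	15	T	G	NA	0.3711
mismatch	16	A	C	NA	0.3368
mismatch	16	A	G	NA	0.6353
mismatch	16	A	T	NA	0.3368
mismatch	16	C	A	NA	0.3368
mismatch	16	C	G	NA	0.3368
mismatch	16	C	T	NA	0.6353
mismatch	16	G	A	NA	0.8011
mismatch	16	G	C	NA	0.3368
mismatch	16	G	T	NA	0.3368
mismatch	16	T	A	NA	0.3368
mismatch	16	T	C	NA	0.6353
mismatch	16	T	G	NA	0.3368
mismatch	17	A	C	NA	0.3026
mismatch	17	A	G	NA	0.6164
mismatch	17	A	T	NA	0.3026
mismatch	17	C	A	NA	0.3026
mismatch	17	C	G	NA	0.3026
mismatch	17	C	T	NA	0.6164
mismatch	17	G	A	NA	0.7908
mismatch	17	G	C	NA	0.3026
mismatch	17	G	T	NA	0.3026
mismatch	17	T	A	NA	0.3026
mismatch	17	T	C	NA	0.6164
mismatch	17	T	G	NA	0.3026
mismatch	18	A	C	NA	0.2684
mismatch	18	A	G	NA	0.5976
mismatch	18	A	T	NA	0.2684
mismatch	18	C	A	NA	0.2684
mismatch	18	C	G	NA	0.2684
mismatch	18	C	T	NA	0.5976
mismatch	18	G	A	NA	0.7805
mismatch	18	G	C	NA	0.2684
mismatch	18	G	T	NA	0.2684
mismatch	18	T	A	NA	0.2684
mismatch	18	T	C	NA	0.5976
mismatch	18	T	G	NA	0.2684
mismatch	19	A	C	NA	0.2342
mismatch	19	A	G	NA	0.5788
mismatch	19	A	T	NA	0.2342
mismatch	19	C	A	NA	0.2342
mismatch	19	C	G	NA	0.2342
mismatch	19	C	T	NA	0.5788
mismatch	19	G	A	NA	0.7703
mismatch	19	G	C	NA	0.2342
mismatch	19	G	T	NA	0.2342
mismatch	19	T	A	NA	0.2342
mismatch	19	T	C	NA	0.5788
mismatch	19	T	G	NA	0.2342
mismatch	20	A	C	NA	0.2
mismatch	20	A	G	NA	0.56
mismatch	20	A	T	NA	0.2
mismatch	20	C	A	NA	0.2
mismatch	20	C	G	NA	0.2
mismatch	20	C	T	NA	0.56
mismatch	20	G	A	NA	0.76
mismatch	20	G	C	NA	0.2
mismatch	20	G	T	NA	0.2
mismatch	20	T	A	NA	0.2
mismatch	20	T	C	NA	0.56
mismatch	20	T	G	NA	0.2
pam	NA	NA	NA	AA	0
pam	NA	NA	NA	CA	0
pam	NA	NA	NA	GA	0.0694
pam	NA	NA	NA	TA	0
pam	NA	NA	NA	AC	0
pam	NA	NA	NA	CC	0
pam	NA	NA	NA	GC	0.0222
pam	NA	NA	NA	TC	0
pam	NA	NA	NA	AG	0.2593
pam	NA	NA	NA	CG	0.1071
pam	NA	NA	NA	GG	1
pam	NA	NA	NA	TG	0.039
pam	NA	NA	NA	AT	0
pam	NA	NA	NA	CT	0
pam	NA	NA	NA	GT	0.0161
pam	NA	NA	NA	TT	0
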