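# Per-gene nucleotide differences between the B. mori C108 and Chinese
# B. mandarina mitochondrial genomes (tRNA genes excluded). bp is the
# B. mori gene length; bp_alt the Chinese B. mandarina length where the
# two differ.
region	bp	bp_alt	strand	category	A-G	T-C	T-A	C-A	T-G	C-G
nad2	1023	NA	major	protein	2	13	2	3	0	0
cox1	1535	NA	major	protein	7	15	4	4	2	1
cox2	682	NA	major	protein	0	9	3	2	0	0
atp8	162	NA	major	protein	0	2	0	0	0	0
atp6	678	NA	major	protein	0	6	3	2	1	0
cox3	789	NA	major	protein	3	20	7	2	1	0
nad3	351	NA	major	protein	1	6	1	1	0	0
nad6	531	NA	major	protein	0	4	1	0	0	0
cob	1152	1158	major	protein	9	26	7	3	4	1
nad5	1719	NA	minor	protein	25	4	5	0	4	1
nad4	1341	NA	minor	protein	13	7	7	0	4	1
nad4L	291	NA	minor	protein	3	0	3	0	3	0
nad1	945	NA	minor	protein	7	2	1	0	3	3
lrRNA	1378	1350	minor	rRNA	12	1	4	0	1	0
srRNA	783	784	minor	rRNA	3	1	7	1	0	0
at_rich	494	484	minor	at_rich	7	0	5	1	0	0
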