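# SYNTHETIC stand-in antennal expression table (FPKM) for the 23-receptor
# screen repertoire. Receptor names follow the screen; FPKM values are
# fabricated placeholders with the qualitative worker-bias structure of
# antennal transcriptomes, NOT measured values. Empty worker_fpkm marks a
# receptor with no expression data (excluded from receptivity, not zeroed).
receptor	worker_fpkm	male_fpkm
HsOr13	22.4	3.1
HsOr16	4.2	6.8
HsOr55	11.0	1.9
HsOr62	3.5	4.9
HsOr70	35.6	2.2
HsOr84	8.9	0.7
HsOr101	14.3	2.6
HsOr115	27.1	1.4
HsOr129	9.8	1.1
HsOr139	18.5	2.9
HsOr152	41.2	0.9
HsOr157	25.7	3.3
HsOr165	7.6	1.6
HsOr178	5.4	0.8
HsOr187	12.9	2.1
HsOr191	30.2	1.7
HsOr196	16.8	2.4
HsOr203	6.1	1.2
HsOr213	21.3	2.8
HsOr219	2.8	19.6
HsOr225	9.2	1.5
HsOr240	33.9	2.0
HsOr271		1.3
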