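pair	highdose_avg	lowdose_avg	sr	xfel	hd_step4	hd_step3	hd_step2	hd_step1	hd_initial	ld_step4	ld_step3	ld_step2	ld_step1	ld_initial
Mn1-Mn2	2.8	2.9	2.8	2.7	2.8	2.8	2.8	2.8	2.8	2.9	2.9	2.9	2.8	3.0
Mn1-Mn3	3.4	3.2	3.3	3.2	3.4	3.4	3.4	3.4	3.5	3.2	3.2	3.2	3.2	3.4
Mn1-Mn4	5.0	5.1	5.0	5.0	5.0	5.0	5.0	5.0	5.0	5.1	5.1	5.1	5.0	5.3
Mn2-Mn3	3.1	2.9	2.9	2.7	3.1	3.1	3.1	3.1	3.1	2.9	2.9	2.9	2.9	2.8
Mn2-Mn4	5.6	5.4	5.4	5.2	5.7	5.7	5.7	5.6	5.4	5.5	5.5	5.4	5.4	5.4
Mn3-Mn4	3.0	3.0	3.0	2.9	3.0	3.0	3.0	2.9	2.7	3.0	3.0	3.0	3.0	3.1
Mn1-Ca	3.5	3.6	3.5	3.5	3.6	3.5	3.5	3.5	3.5	3.6	3.6	3.6	3.6	3.8
Mn2-Ca	3.5	3.4	3.4	3.3	3.5	3.5	3.5	3.5	3.3	3.4	3.4	3.4	3.4	3.4
Mn3-Ca	3.3	3.5	3.4	3.4	3.3	3.3	3.3	3.3	3.0	3.5	3.5	3.4	3.5	3.4
Mn4-Ca	3.7	3.8	3.8	3.8	3.7	3.7	3.7	3.7	3.6	3.8	3.8	3.7	3.8	3.9
Mn1-O1	2.1	1.8	1.9	1.8	2.1	2.1	2.1	2.1	2.3	1.8	1.8	1.8	1.8	2.1
Mn1-O3	2.1	1.9	1.8	1.9	2.1	2.1	2.1	2.1	2.3	1.9	1.9	1.9	1.9	1.9
Mn1-O5	2.7	2.7	2.6	2.7	2.7	2.7	2.7	2.8	2.6	2.7	2.7	2.7	2.7	2.9
Mn2-O1	2.2	1.9	2.1	1.8	2.2	2.2	2.2	2.2	2.2	2.0	2.0	1.9	1.9	2.1
Mn2-O2	2.2	1.8	2.1	1.8	2.2	2.2	2.2	2.2	2.5	1.8	1.8	1.8	1.8	2.5
Mn2-O3	2.3	2.0	2.1	2.0	2.3	2.3	2.3	2.3	2.4	2.0	2.0	2.0	2.0	2.0
Mn3-O2	2.2	1.8	1.9	1.9	2.2	2.2	2.2	2.1	2.0	1.8	1.8	1.8	1.9	2.1
Mn3-O3	2.5	2.1	2.1	2.1	2.5	2.5	2.4	2.4	2.5	2.1	2.1	2.1	2.1	2.0
Mn3-O4	2.3	2.1	2.1	1.9	2.3	2.3	2.3	2.3	2.4	2.2	2.1	2.1	2.0	2.7
Mn3-O5	2.6	2.3	2.4	2.2	2.6	2.6	2.6	2.5	2.6	2.4	2.3	2.3	2.2	2.6
Mn4-O4	1.8	1.9	2.1	2.0	1.8	1.8	1.8	1.8	2.0	1.9	1.9	1.9	2.0	2.1
Mn4-O5	2.5	2.5	2.5	2.3	2.5	2.5	2.5	2.4	2.6	2.5	2.5	2.5	2.4	2.7
Mn4-W1	2.4	2.3	2.2	2.3	2.4	2.4	2.4	2.4	2.5	2.3	2.3	2.4	2.3	2.3
Mn4-W2	2.0	2.2	2.2	2.1	2.1	2.0	2.0	2.1	2.1	2.2	2.2	2.2	2.2	1.8
Ca-O1	2.6	2.7	2.4	2.6	2.6	2.6	2.6	2.6	2.6	2.7	2.7	2.7	2.6	2.5
Ca-O2	2.4	2.7	2.5	2.7	2.4	2.4	2.4	2.4	2.4	2.7	2.7	2.7	2.7	2.7
Ca-O5	2.7	2.6	2.7	2.5	2.7	2.7	2.7	2.7	2.7	2.6	2.6	2.6	2.6	2.6
Ca-W3	2.8	2.6	2.4	2.6	2.8	2.8	2.8	2.8	2.8	2.6	2.6	2.6	2.5	2.6
Ca-W4	2.9	2.7	2.5	2.5	2.9	2.9	2.9	2.9	2.9	2.7	2.7	2.7	2.7	2.7
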