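fa	condition	mean	sd	n
14:0	9C	1.0	0.1	3
14:0	22C	1.2	0.3	3
14:0	27C	1.1	0.1	3
16:0	9C	20.6	1.5	3
16:0	22C	23.0	1.9	3
16:0	27C	41.8	3.5	3
16:1 Δ7	9C	1.9	0.6	3
16:1 Δ7	22C	0.4	0.1	3
16:1 Δ7	27C	0.2	0.2	3
16:1 Δ9	9C	NA	NA	3
16:1 Δ9	22C	1.0	0.1	3
16:1 Δ9	27C	0.3	0.3	3
16:2 Δ7,10	9C	1.8	0.1	3
16:2 Δ7,10	22C	2.7	0.1	3
16:2 Δ7,10	27C	0.4	0.2	3
16:3 Δ7,10,13	9C	6.0	0.9	3
16:3 Δ7,10,13	22C	1.7	0.4	3
16:3 Δ7,10,13	27C	0.1	0.1	3
18:0	9C	2.4	0.7	3
18:0	22C	0.8	0.6	3
18:0	27C	3.4	1.3	3
18:1 Δ9	9C	5.7	1.3	3
18:1 Δ9	22C	7.3	0.1	3
18:1 Δ9	27C	25.4	3.0	3
18:1 Δ11	9C	1.3	0.1	3
18:1 Δ11	22C	2.6	0.3	3
18:1 Δ11	27C	1.4	0.1	3
18:2 Δ9,12	9C	17.1	0.9	3
18:2 Δ9,12	22C	36.1	2.2	3
18:2 Δ9,12	27C	21.2	4.0	3
18:3 Δ9,12,15	9C	41.6	2.0	3
18:3 Δ9,12,15	22C	22.8	1.4	3
18:3 Δ9,12,15	27C	3.0	1.1	3
UI	9C	1.892	0.075	3
UI	22C	1.623	0.066	3
UI	27C	0.802	0.095	3
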