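batch_id	channel	sample_id	participant	condition	concentration_ppm	is_reference_pool
batch1	126	1.P	1	unstimulated	NA	TRUE
batch1	127_N	2.P	2	unstimulated	NA	TRUE
batch1	127_C	2.2	2	cinnamaldehyde_180	180	FALSE
batch1	128_N	1.2	1	nonivamide_0.6	0.6	FALSE
batch1	128_C	1.1	1	cinnamaldehyde_300	300	FALSE
batch1	129_N	1.1	1	pg_30000	30000	FALSE
batch1	129_C	2.3	2	menthol_500	500	FALSE
batch1	130_N	2.2	2	pg_18000	18000	FALSE
batch1	130_C	2.2	2	menthol_300	300	FALSE
batch1	131	1.2	1	nonivamide_1	1	FALSE
batch2	126	1.P	1	unstimulated	NA	TRUE
batch2	127_N	2.P	2	unstimulated	NA	TRUE
batch2	127_C	1.2	1	cinnamaldehyde_180	180	FALSE
batch2	128_N	2.1	2	nonivamide_0.6	0.6	FALSE
batch2	128_C	1.3	1	cinnamaldehyde_300	300	FALSE
batch2	129_N	2.2	2	pg_30000	30000	FALSE
batch2	129_C	1.2	1	menthol_500	500	FALSE
batch2	130_N	2.1	2	pg_18000	18000	FALSE
batch2	130_C	1.2	1	menthol_300	300	FALSE
batch2	131	2.1	2	nonivamide_1	1	FALSE
batch3	126	1.P	1	unstimulated	NA	TRUE
batch3	127_N	2.P	2	unstimulated	NA	TRUE
batch3	127_C	1.3	1	cinnamaldehyde_180	180	FALSE
batch3	128_N	1.1	1	nonivamide_0.6	0.6	FALSE
batch3	128_C	2.1	2	cinnamaldehyde_300	300	FALSE
batch3	129_N	2.3	2	pg_30000	30000	FALSE
batch3	129_C	1.3	1	menthol_500	500	FALSE
batch3	130_N	1.3	1	pg_18000	18000	FALSE
batch3	130_C	2.1	2	menthol_300	300	FALSE
batch3	131	1.3	1	nonivamide_1	1	FALSE
batch4	126	1.P	1	unstimulated	NA	TRUE
batch4	127_N	2.P	2	unstimulated	NA	TRUE
batch4	127_C	2.1	2	cinnamaldehyde_180	180	FALSE
batch4	128_N	2.2	2	nonivamide_0.6	0.6	FALSE
batch4	128_C	2.2	2	cinnamaldehyde_300	300	FALSE
batch4	129_N	1.2	1	pg_30000	30000	FALSE
batch4	129_C	2.2	2	menthol_500	500	FALSE
batch4	130_N	1.1	1	pg_18000	18000	FALSE
batch4	130_C	1.3	1	menthol_300	300	FALSE
batch4	131	2.2	2	nonivamide_1	1	FALSE
batch5	126	1.P	1	unstimulated	NA	TRUE
batch5	127_N	2.P	2	unstimulated	NA	TRUE
batch5	127_C	1.1	1	cinnamaldehyde_180	180	FALSE
batch5	128_N	2.3	2	nonivamide_0.6	0.6	FALSE
batch5	128_C	1.2	1	cinnamaldehyde_300	300	FALSE
batch5	129_N	1.3	1	pg_30000	30000	FALSE
batch5	129_C	2.1	2	menthol_500	500	FALSE
batch5	130_N	2.3	2	pg_18000	18000	FALSE
batch5	130_C	1.1	1	menthol_300	300	FALSE
batch5	131	1.1	1	nonivamide_1	1	FALSE
batch6	126	1.P	1	unstimulated	NA	TRUE
batch6	127_N	2.P	2	unstimulated	NA	TRUE
batch6	127_C	2.3	2	cinnamaldehyde_180	180	FALSE
batch6	128_N	1.3	1	nonivamide_0.6	0.6	FALSE
batch6	128_C	2.3	2	cinnamaldehyde_300	300	FALSE
batch6	129_N	2.1	2	pg_30000	30000	FALSE
batch6	129_C	1.1	1	menthol_500	500	FALSE
batch6	130_N	2.1	2	pg_18000	18000	FALSE
batch6	130_C	2.3	2	menthol_300	300	FALSE
batch6	131	2.3	2	nonivamide_1	1	FALSE
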