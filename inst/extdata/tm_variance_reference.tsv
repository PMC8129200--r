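n	d	variance_without_ns	variance_with_ns
8	3	5.9351	5.0461
8	4	5.2979	4.9945
8	5	6.6136	3.5621
8	6	5.4233	3.5888
8	7	8.3799	4.2264
9	3	4.7033	4.5800
9	4	4.8000	4.4041
9	5	4.7655	3.9916
9	6	3.6546	2.8110
9	7	4.8876	1.4578
10	3	4.4705	4.0754
10	4	4.5131	4.0554
10	5	4.8233	4.2452
10	6	5.0288	4.2037
10	7	3.3062	3.9066
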