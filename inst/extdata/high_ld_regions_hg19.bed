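# Canonical long-range high-LD regions (hg19), 0-based half-open intervals.
# Default exclusion list for ancestry PCA; replaceable via configuration.
1	48000000	52000000
2	86000000	100500000
2	134500000	138000000
2	183000000	190000000
3	47500000	50000000
3	83500000	87000000
3	89000000	97500000
5	44500000	50500000
5	98000000	100500000
5	129000000	132000000
5	135500000	138500000
6	25500000	33500000
6	57000000	64000000
6	140000000	142500000
7	55000000	66000000
8	8000000	12000000
8	43000000	50000000
8	112000000	115000000
10	37000000	43000000
11	46000000	57000000
11	87500000	90500000
12	33000000	40000000
12	109500000	112000000
20	32000000	34500000
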