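kegg_fib_01	synthetic fibrosis-associated membership fixture	Mmp7	Tgfb3	Id1	Hsd17b6	Cyp1a1	Fst	Cxcl1	Retsat	Il1r2	Itgb21
kegg_fib_02	synthetic fibrosis-associated membership fixture	Tgfb3	Id1	Cxcl1	Il1r2	Itgb21
kegg_fib_03	synthetic fibrosis-associated membership fixture	Tgfb3
kegg_fib_04	synthetic fibrosis-associated membership fixture	Tgfb3
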