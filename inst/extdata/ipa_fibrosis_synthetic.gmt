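ipa_fib_01	synthetic fibrosis-associated membership fixture	Mmp7	Tgfb3	Cxcl1	Mmp13	Ces1d	Il1r2
ipa_fib_02	synthetic fibrosis-associated membership fixture	Mmp7	Tgfb3	Cxcl1	Mmp13	Il1r2
ipa_fib_03	synthetic fibrosis-associated membership fixture	Mmp7	Tgfb3	Mmp13	Il1r2
ipa_fib_04	synthetic fibrosis-associated membership fixture	Mmp7	Tgfb3	Mmp13	Il1r2
ipa_fib_05	synthetic fibrosis-associated membership fixture	Mmp7	Tgfb3	Mmp13	Il1r2
ipa_fib_06	synthetic fibrosis-associated membership fixture	Il1r2
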