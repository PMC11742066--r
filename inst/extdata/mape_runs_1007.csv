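run,EO,GWO,HGSO,BMO,MRFO,SSA,WOA,HHO
1,0.0033643,0.0033647,0.0033689,0.0033578,0.0033652,0.0033650,0.0035089,0.0033862
2,0.0033643,0.0033646,0.0033689,0.0033578,0.0033643,0.0033650,0.0035084,0.0033859
3,0.0033643,0.0033646,0.0033689,0.0033578,0.0033643,0.0033650,0.0035082,0.0033843
4,0.0033643,0.0033646,0.0033679,0.0033578,0.0033643,0.0033644,0.0035080,0.0033837
5,0.0033642,0.0033646,0.0033679,0.0033578,0.0033643,0.0033644,0.0035080,0.0033837
6,0.0033642,0.0033646,0.0033679,0.0033578,0.0033641,0.0033641,0.0035080,0.0033836
7,0.0033642,0.0033644,0.0033679,0.0033578,0.0033641,0.0033641,0.0035080,0.0032486
8,0.0033642,0.0033643,0.0033679,0.0033578,0.0033641,0.0033640,0.0035080,0.0032469
9,0.0033640,0.0033642,0.0033679,0.0033578,0.0033641,0.0033640,0.0035080,0.0032430
10,0.0033640,0.0033642,0.0033666,0.0033578,0.0033641,0.0033640,0.0035080,0.0032429
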