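"name","canonical_source_order"
"glucose","6 1 5 2 4 3 12 11 8 10 9 7"
"G6P","6 1 5 2 4 3 11 8 10 9 7 15 16 14 12 13"
"F6P","6 1 5 4 3 2 7 11 10 9 8 15 16 14 12 13"
"FBP","6 1 5 4 3 2 11 10 9 8 15 16 19 20 14 18 12 7 13 17"
"DHAP","3 1 2 6 5 9 10 8 4 7"
"GAP","3 1 2 5 4 9 10 8 6 7"
"BPG","3 2 1 6 4 14 15 10 11 13 9 7 5 12 8"
"3PG","3 2 1 6 5 4 10 11 9 7 8"
"2PG","3 2 1 7 5 4 10 11 9 6 8"
"PEP","3 2 1 5 4 9 10 8 6 7"
"pyruvate","3 2 1 5 6 4"
"acetyl-CoA","2 1 3 4"
"CO2","1 2 3"
"water","1"
"ammonia","1"
"glutamine","3 4 2 5 1 8 10 7 9 6"
"glutamate","3 4 2 5 1 8 10 7 9 6"
"AKG","3 4 2 5 1 10 7 8 9 6"
"GABA","3 2 4 1 7 6 5"
"fumarate","2 3 1 4 6 8 5 7"
"malate","3 2 4 1 9 8 6 7 5"
"benzene","1 6 2 5 3 4"
"ATP","10 1 5 9 8 7 3 4 6 2 15 11 13 12 14 18 17 30 31 22 26 29 21 25 16 19 27 23 28 20 24"
"ADP","10 1 5 9 8 7 3 4 6 2 15 11 13 12 14 18 17 26 27 22 25 21 16 19 23 24 20"
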