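code,name
1,cereals
2,roots and tubers
3,vegetables
4,mushroom and seafood (plant)
5,"meat, poultry, and offal"
6,eggs
7,fish and seafood
8,pulses and legumes
9,nuts
10,dairy products
11,fruits
12,"miscellaneous (condiments, snacks, beverages)"
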