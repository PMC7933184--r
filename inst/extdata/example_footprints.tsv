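# Binary example footprints (weight 1 = member).
# upright: the linear surface patch outlining the upright binding mode.
# key_arginines: the arginine epitope of the canonical binding groove.
mode	residue_id	weight
upright	38	1
upright	43	1
upright	44	1
upright	79	1
upright	80	1
upright	105	1
upright	113	1
upright	114	1
upright	162	1
upright	166	1
key_arginines	41	1
key_arginines	78	1
key_arginines	150	1
key_arginines	154	1
key_arginines	162	1
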