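# Chromophore-pocket positions, hbonds library (24 positions; includes
# residues hydrogen-bonding directly to the chromophore)
42, 44, 61, 62, 69, 92, 94, 96, 112, 121, 145, 148, 150, 163, 165, 167, 181, 183, 185, 203, 205, 220, 222, 224
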