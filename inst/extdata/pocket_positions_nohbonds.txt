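# Chromophore-pocket positions, nohbonds library (27 positions; excludes
# residues hydrogen-bonding directly to the chromophore)
14, 16, 18, 42, 44, 46, 61, 64, 66, 68, 69, 72, 108, 110, 112, 119, 123, 145, 150, 163, 165, 167, 181, 185, 201, 220, 224
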