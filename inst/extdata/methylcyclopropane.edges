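# lumped (hydrogen-suppressed) methylcyclopropane: methyl carbon 1 bonded
# to ring atom 2; ring atoms 2, 3, 4 form the 3-cycle
1 2
2 3
2 4
3 4
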