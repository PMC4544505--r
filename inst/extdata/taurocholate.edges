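# coarse-grained trihydroxy bile salt (taurocholate) bead model,
# three-to-one mapping of heavy atoms to beads; 12 beads, 12 bonds
1 2
2 3
2 4
3 5
4 5
5 6
6 7
7 8
8 9
1 10
3 11
4 12
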