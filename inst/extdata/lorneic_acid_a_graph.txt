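# Carbon skeleton of lorneic acid A (17 carbons): linear 16-carbon backbone
# C16 ... C1 with the C-17 methyl branch at C-8. Chain extension begins at
# the C-16/C-15 acetate and terminates at the C-1 carboxyl. No terminal
# hint is needed: the starter methyl C-16 is a degree-1 carbon.
graph lorneic_acid_a
bond 16 15
bond 15 14
bond 14 13
bond 13 12
bond 12 11
bond 11 10
bond 10 9
bond 9 8
bond 8 7
bond 7 6
bond 6 5
bond 5 4
bond 4 3
bond 3 2
bond 2 1
bond 8 17
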