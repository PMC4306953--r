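# Carbon skeleton of akaeolide (22 carbons, C-C bonds only; the lactone and
# ether oxygens are not part of the tiled graph).
#
# SYNTHETIC RECONSTRUCTION: the published atom-to-unit incorporation map is
# figure-only, so this bond list was reconstructed to be consistent with
# (i) the 15-membered carbocyclic framework, (ii) the enrichment sets of
# the three feeding experiments, and (iii) the C5 (propylmalonyl) unit
# carrying the C-3/C-2/C-1 propyl side chain at C-4. Chain extension runs
# C16 -> C15 -> ... -> C4 -> C19 -> C17 -> C18 (carboxyl/lactone carbonyl),
# with methyl branches C-22 at C-14, C-21 at C-12, C-20 at C-8. The
# C16-C17 bond closes the carbocycle and is the post-assembly (aldol) bond;
# because it buries the starter methyl C-16 inside the ring, the file
# carries an explicit terminal hint.
graph akaeolide
terminal 16
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
bond 4 19
bond 19 17
bond 17 18
bond 14 22
bond 12 21
bond 8 20
bond 4 3
bond 3 2
bond 2 1
bond 16 17
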