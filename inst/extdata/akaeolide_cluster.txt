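# Akaeolide biosynthetic PKS cluster (1 loading + 7 extension modules).
# Extender sequence: C2 starter; then C3, C3, C2, C3, C2, C5 (propylmalonyl),
# C2. Annotated reductive complement: four DH/KR modules and one DH/ER/KR
# module; the DH domains of m3 and m6 are catalytically silent
# (active=false), so the mature linear chain keeps beta-hydroxyls there and
# only two of the four potential double bonds survive.
#
# Transcription note: the source annotation attributes the B1-type KR
# fingerprints to "modules 2 and 6" while naming the silent DHs as m3 and
# m6. Under the beta-processing convention used by this package (extension
# module i sets the oxidation of C1 of unit i-1), the hydroxyl-forming KRs
# are the ones co-resident with the silent DHs, i.e. m3 and m6; the ER that
# fixes the alpha-methyl configuration sits in m2. This file keeps the
# stated stereochemical outcomes attached to the stated carbons (C-5 and
# C-11 hydroxyls S, C-4 propyl R, C-12 methyl S) without renumbering the
# text's module indices; the apparent off-by-one is recorded here rather
# than resolved.
cluster akaeolide_bgc
compound akaeolide
module 0 loading
domain AT signature=HAFH
domain ACP
module 1
domain KS
domain AT signature=YASH
domain DH
domain KR fingerprint=B1
domain ACP
module 2
domain KS
domain AT signature=YASH
domain DH
domain ER er_class=Y
domain KR fingerprint=B1
domain ACP
module 3
domain KS
domain AT signature=HAFH
domain DH active=false
domain KR fingerprint=B1
domain ACP
module 4
domain KS
domain AT signature=YASH
domain DH
domain KR fingerprint=B1
domain ACP
module 5
domain KS
domain AT signature=HAFH
domain ACP
module 6
domain KS
domain AT signature=TAGH side_carbons=3
domain DH active=false
domain KR fingerprint=B1
domain ACP
module 7
domain KS
domain AT signature=HAFH
domain ACP
domain TE
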