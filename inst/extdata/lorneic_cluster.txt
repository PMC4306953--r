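# Lorneic acid biosynthetic PKS cluster (1 loading + 7 extension modules).
# AT substrates: acetyl starter on the loading module; malonyl-CoA on m1,
# m2, m3, m5, m6 and m7; methylmalonyl-CoA on m4 (the single C3 extender).
# Reductive complement: DH/ER/KR in m1, m2 and m4; DH/KR in m3, m5, m6 and
# m7 (three saturated methylenes and four double bonds). All KRs are
# B-type, hence all-trans (E) double-bond geometry.
#
# The ER domain of m4 may be non-functional in vivo (the polyolefinic
# intermediate of composition C17H24O2 requires a fifth double bond at its
# position); it is encoded active here, and analyses of that intermediate
# toggle the flag off in memory.
cluster lorneic_bgc
compound lorneic acid A
module 0 loading
domain AT signature=HAFH
domain ACP
module 1
domain KS
domain AT signature=HAFH
domain DH
domain ER er_class=Y
domain KR fingerprint=B1
domain ACP
module 2
domain KS
domain AT signature=HAFH
domain DH
domain ER er_class=Y
domain KR fingerprint=B1
domain ACP
module 3
domain KS
domain AT signature=HAFH
domain DH
domain KR fingerprint=B1
domain ACP
module 4
domain KS
domain AT signature=YASH
domain DH
domain ER er_class=Y
domain KR fingerprint=B1
domain ACP
module 5
domain KS
domain AT signature=HAFH
domain DH
domain KR fingerprint=B1
domain ACP
module 6
domain KS
domain AT signature=HAFH
domain DH
domain KR fingerprint=B1
domain ACP
module 7
domain KS
domain AT signature=HAFH
domain DH
domain KR fingerprint=B1
domain ACP
domain TE
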