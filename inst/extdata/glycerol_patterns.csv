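# Per-atom 13C enrichment fractions for E. coli grown on [2-13C]-glycerol
# (scheme glycerol_2) or [1,3-13C]-glycerol (scheme glycerol_1_3).
# APPROXIMATE values, reconstructed from biosynthetic precursor mapping
# after LeMaster & Kushlan, J Magn Reson B (1996) and Castellani et al.,
# Nature (2002).  Glycolytic amino acids carry clean patterns (pyruvate
# C2 labeled by 2-glycerol; C1/C3 by 1,3-glycerol); TCA- and PPP-derived
# amino acids are partially scrambled by cycling and are encoded as
# fractional enrichments.  Version 1; values can be overridden from a
# scheme descriptor (field enrichment_overrides).
scheme,res,atom,fraction
glycerol_2,A,CA,0.95
glycerol_2,A,CB,0.02
glycerol_2,A,C,0.02
glycerol_1_3,A,CA,0.02
glycerol_1_3,A,CB,0.95
glycerol_1_3,A,C,0.95
glycerol_2,S,CA,0.95
glycerol_2,S,CB,0.02
glycerol_2,S,C,0.02
glycerol_1_3,S,CA,0.02
glycerol_1_3,S,CB,0.95
glycerol_1_3,S,C,0.95
glycerol_2,C,CA,0.95
glycerol_2,C,CB,0.02
glycerol_2,C,C,0.02
glycerol_1_3,C,CA,0.02
glycerol_1_3,C,CB,0.95
glycerol_1_3,C,C,0.95
glycerol_2,G,CA,0.95
glycerol_2,G,C,0.02
glycerol_1_3,G,CA,0.02
glycerol_1_3,G,C,0.95
glycerol_2,V,CA,0.95
glycerol_2,V,CB,0.95
glycerol_2,V,CG1,0.02
glycerol_2,V,CG2,0.02
glycerol_2,V,C,0.02
glycerol_1_3,V,CA,0.02
glycerol_1_3,V,CB,0.02
glycerol_1_3,V,CG1,0.95
glycerol_1_3,V,CG2,0.95
glycerol_1_3,V,C,0.95
glycerol_2,L,CA,0.05
glycerol_2,L,CB,0.95
glycerol_2,L,CG,0.95
glycerol_2,L,CD1,0.02
glycerol_2,L,CD2,0.02
glycerol_2,L,C,0.95
glycerol_1_3,L,CA,0.95
glycerol_1_3,L,CB,0.02
glycerol_1_3,L,CG,0.02
glycerol_1_3,L,CD1,0.95
glycerol_1_3,L,CD2,0.95
glycerol_1_3,L,C,0.02
glycerol_2,I,CA,0.40
glycerol_2,I,CB,0.90
glycerol_2,I,CG1,0.20
glycerol_2,I,CG2,0.05
glycerol_2,I,CD1,0.10
glycerol_2,I,C,0.20
glycerol_1_3,I,CA,0.50
glycerol_1_3,I,CB,0.05
glycerol_1_3,I,CG1,0.60
glycerol_1_3,I,CG2,0.90
glycerol_1_3,I,CD1,0.90
glycerol_1_3,I,C,0.60
glycerol_2,D,CA,0.50
glycerol_2,D,CB,0.20
glycerol_2,D,CG,0.10
glycerol_2,D,C,0.10
glycerol_1_3,D,CA,0.15
glycerol_1_3,D,CB,0.75
glycerol_1_3,D,CG,0.70
glycerol_1_3,D,C,0.70
glycerol_2,N,CA,0.50
glycerol_2,N,CB,0.20
glycerol_2,N,CG,0.10
glycerol_2,N,C,0.10
glycerol_1_3,N,CA,0.15
glycerol_1_3,N,CB,0.75
glycerol_1_3,N,CG,0.70
glycerol_1_3,N,C,0.70
glycerol_2,T,CA,0.50
glycerol_2,T,CB,0.20
glycerol_2,T,CG2,0.10
glycerol_2,T,C,0.10
glycerol_1_3,T,CA,0.15
glycerol_1_3,T,CB,0.75
glycerol_1_3,T,CG2,0.70
glycerol_1_3,T,C,0.70
glycerol_2,M,CA,0.50
glycerol_2,M,CB,0.20
glycerol_2,M,CG,0.10
glycerol_2,M,CE,0.10
glycerol_2,M,C,0.10
glycerol_1_3,M,CA,0.15
glycerol_1_3,M,CB,0.75
glycerol_1_3,M,CG,0.70
glycerol_1_3,M,CE,0.30
glycerol_1_3,M,C,0.70
glycerol_2,K,CA,0.50
glycerol_2,K,CB,0.20
glycerol_2,K,CG,0.50
glycerol_2,K,CD,0.30
glycerol_2,K,CE,0.20
glycerol_2,K,C,0.10
glycerol_1_3,K,CA,0.20
glycerol_1_3,K,CB,0.60
glycerol_1_3,K,CG,0.30
glycerol_1_3,K,CD,0.50
glycerol_1_3,K,CE,0.50
glycerol_1_3,K,C,0.70
glycerol_2,E,CA,0.50
glycerol_2,E,CB,0.20
glycerol_2,E,CG,0.05
glycerol_2,E,CD,0.90
glycerol_2,E,C,0.10
glycerol_1_3,E,CA,0.15
glycerol_1_3,E,CB,0.70
glycerol_1_3,E,CG,0.90
glycerol_1_3,E,CD,0.05
glycerol_1_3,E,C,0.70
glycerol_2,Q,CA,0.50
glycerol_2,Q,CB,0.20
glycerol_2,Q,CG,0.05
glycerol_2,Q,CD,0.90
glycerol_2,Q,C,0.10
glycerol_1_3,Q,CA,0.15
glycerol_1_3,Q,CB,0.70
glycerol_1_3,Q,CG,0.90
glycerol_1_3,Q,CD,0.05
glycerol_1_3,Q,C,0.70
glycerol_2,P,CA,0.50
glycerol_2,P,CB,0.20
glycerol_2,P,CG,0.05
glycerol_2,P,CD,0.90
glycerol_2,P,C,0.10
glycerol_1_3,P,CA,0.15
glycerol_1_3,P,CB,0.70
glycerol_1_3,P,CG,0.90
glycerol_1_3,P,CD,0.05
glycerol_1_3,P,C,0.70
glycerol_2,R,CA,0.50
glycerol_2,R,CB,0.20
glycerol_2,R,CG,0.05
glycerol_2,R,CD,0.90
glycerol_2,R,CZ,0.10
glycerol_2,R,C,0.10
glycerol_1_3,R,CA,0.15
glycerol_1_3,R,CB,0.70
glycerol_1_3,R,CG,0.90
glycerol_1_3,R,CD,0.05
glycerol_1_3,R,CZ,0.10
glycerol_1_3,R,C,0.70
glycerol_2,F,CA,0.95
glycerol_2,F,CB,0.05
glycerol_2,F,CG,0.90
glycerol_2,F,CD1,0.10
glycerol_2,F,CD2,0.10
glycerol_2,F,CE1,0.30
glycerol_2,F,CE2,0.30
glycerol_2,F,CZ,0.40
glycerol_2,F,C,0.05
glycerol_1_3,F,CA,0.05
glycerol_1_3,F,CB,0.95
glycerol_1_3,F,CG,0.05
glycerol_1_3,F,CD1,0.50
glycerol_1_3,F,CD2,0.50
glycerol_1_3,F,CE1,0.40
glycerol_1_3,F,CE2,0.40
glycerol_1_3,F,CZ,0.30
glycerol_1_3,F,C,0.95
glycerol_2,Y,CA,0.95
glycerol_2,Y,CB,0.05
glycerol_2,Y,CG,0.90
glycerol_2,Y,CD1,0.10
glycerol_2,Y,CD2,0.10
glycerol_2,Y,CE1,0.30
glycerol_2,Y,CE2,0.30
glycerol_2,Y,CZ,0.40
glycerol_2,Y,C,0.05
glycerol_1_3,Y,CA,0.05
glycerol_1_3,Y,CB,0.95
glycerol_1_3,Y,CG,0.05
glycerol_1_3,Y,CD1,0.50
glycerol_1_3,Y,CD2,0.50
glycerol_1_3,Y,CE1,0.40
glycerol_1_3,Y,CE2,0.40
glycerol_1_3,Y,CZ,0.30
glycerol_1_3,Y,C,0.95
glycerol_2,W,CA,0.95
glycerol_2,W,CB,0.05
glycerol_2,W,CG,0.30
glycerol_2,W,CD1,0.30
glycerol_2,W,CD2,0.30
glycerol_2,W,CE2,0.30
glycerol_2,W,CE3,0.30
glycerol_2,W,CZ2,0.30
glycerol_2,W,CZ3,0.30
glycerol_2,W,CH2,0.30
glycerol_2,W,C,0.05
glycerol_1_3,W,CA,0.05
glycerol_1_3,W,CB,0.95
glycerol_1_3,W,CG,0.40
glycerol_1_3,W,CD1,0.40
glycerol_1_3,W,CD2,0.40
glycerol_1_3,W,CE2,0.40
glycerol_1_3,W,CE3,0.40
glycerol_1_3,W,CZ2,0.40
glycerol_1_3,W,CZ3,0.40
glycerol_1_3,W,CH2,0.40
glycerol_1_3,W,C,0.95
glycerol_2,H,CA,0.30
glycerol_2,H,CB,0.25
glycerol_2,H,CG,0.30
glycerol_2,H,CD2,0.30
glycerol_2,H,CE1,0.30
glycerol_2,H,C,0.15
glycerol_1_3,H,CA,0.50
glycerol_1_3,H,CB,0.60
glycerol_1_3,H,CG,0.40
glycerol_1_3,H,CD2,0.40
glycerol_1_3,H,CE1,0.50
glycerol_1_3,H,C,0.70
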