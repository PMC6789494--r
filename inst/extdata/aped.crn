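# APED model (activation-polymerization-epimerization-depolymerization)
# of Plasson et al., generic stereoselectivity: the hetero-selective rate
# labels (kap = alpha*p, kbh = beta*h, kge = gamma*e) are independent of
# their homochiral counterparts (kp, kh, ke).  Activated monomers L*, D*
# map to Lx, Dx.  Order-4 pseudochiral: pairs (L,D), (Lx,Dx), (LL,DD),
# (LD,DL).
pair L:D
pair Lx:Dx
pair LL:DD
pair LD:DL
L -> Lx | ka
D -> Dx | ka
Lx -> L | kb
Dx -> D | kb
LL -> L + L | kh
DD -> D + D | kh
DL -> L + D | kbh
LD -> L + D | kbh
Lx + L -> LL | kp
Dx + D -> DD | kp
Dx + L -> DL | kap
Lx + D -> LD | kap
LD -> DD | ke
DL -> LL | ke
DD -> LD | kge
LL -> DL | kge
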