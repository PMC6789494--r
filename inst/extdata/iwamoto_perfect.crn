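# Iwamoto's Michaelis-Menten-type model, perfect (fully stereospecific)
# conditions.  Only A, L, D, E_L and E_D are dynamic variables; the
# substrate P, product Q and the enzyme-substrate complexes Z_L, Z_D are
# held constant.  E_L -> EL etc.
constant P Q ZL ZD
pair L:D
pair EL:ED
pair ZL:ZD
dual k2~k4
dual k3~k5
dual k6~k8
dual k7~k9
dual k10~k12
dual k11~k13
P <-> A | k0, k1
A + L <-> 2 L | k2, k3
A + D <-> 2 D | k4, k5
L + EL <-> ZL | k6, k7
D + ED <-> ZD | k8, k9
ZL <-> EL + Q | k10, k11
ZD <-> ED + Q | k12, k13
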