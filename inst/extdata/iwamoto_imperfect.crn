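# Iwamoto model, imperfect conditions: adds the stereoselective
# autocatalysis channels (R1a/R2a) and the stereospecificity-breaking
# enzyme channels (R3a/R4a, complexes Y_L, Y_D) to the perfect network.
# Rate constants are distinct between the a-channels and their perfect
# counterparts (k2 = k4 != k2a = k4a, etc.), as the original author
# assumes.
constant P Q ZL ZD YL YD
pair L:D
pair EL:ED
pair ZL:ZD
pair YL:YD
dual k2~k4
dual k3~k5
dual k2a~k4a
dual k3a~k5a
dual k6~k8
dual k7~k9
dual k6a~k8a
dual k7a~k9a
dual k10~k12
dual k11~k13
dual k10a~k12a
dual k11a~k13a
P <-> A | k0, k1
A + L <-> 2 L | k2, k3
A + L <-> L + D | k2a, k3a
A + D <-> 2 D | k4, k5
A + D <-> D + L | k4a, k5a
L + EL <-> ZL | k6, k7
L + ED <-> YD | k6a, k7a
D + ED <-> ZD | k8, k9
D + EL <-> YL | k8a, k9a
ZL <-> EL + Q | k10, k11
YL <-> EL + Q | k10a, k11a
ZD <-> ED + Q | k12, k13
YD <-> ED + Q | k12a, k13a
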