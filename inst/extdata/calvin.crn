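# Calvin's abstract autocatalytic model: order-2 pseudochiral network with
# autocatalysis (k0/k1), its reverse (k2/k3), racemization (k4/k5) and
# enantiomeric conversion (k6..k9).  A classical negative control: it has
# no symmetry-breaking states.
pair L1:D1
pair L2:D2
dual k0~k1
dual k2~k3
dual k4~k5
dual k6~k7
dual k8~k9
L1 + L2 -> 2 L2 | k0
D1 + D2 -> 2 D2 | k1
2 L2 -> L1 + L2 | k2
2 D2 -> D1 + D2 | k3
L1 -> D1 | k4
D1 -> L1 | k5
L1 -> L2 | k6
D1 -> D2 | k7
L2 -> L1 | k8
D2 -> D1 | k9
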