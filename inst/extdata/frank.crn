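# Frank's minimal autocatalytic model of absolute asymmetric synthesis.
# The feed A is held constant (pool chemical approximation); the inert
# product P is likewise outside the dynamics.
constant A P
pair L:D
dual k1~k2
L + A -> 2 L | k1
D + A -> 2 D | k2
L + D -> P | k3
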