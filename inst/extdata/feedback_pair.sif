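# Synthetic illustrative network: one stimulus A, two mutually activating
# latent nodes B1/B2 (a feedback pair), one measured readout C.
# B1 and B2 share identical responses under every condition, so
# compartmentalization groups them.
A 1 B1
A 1 B2
B1 1 B2
B2 1 B1
B1 1 C
B2 1 C
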