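# Synthetic illustrative network: two stimuli A1/A2 fan out onto two latent
# nodes B1/B2, which feed two separate readouts C1/C2. If the data activate
# C1 only under A1 and C2 only under A2, grouping B1/B2 is over-aggressive:
# the compartmentalized model cannot fit both readouts.
A1 1 B1
A1 1 B2
A2 1 B1
A2 1 B2
B1 1 C1
B2 1 C2
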