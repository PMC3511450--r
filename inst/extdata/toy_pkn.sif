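# Toy signaling model: stimuli TGFa, TNFa; inhibitor nodes MEK12i, PI3Ki;
# latent PI3K; measured signals MEK12, ERK12, AKT, JNK, P38.
# 10 reactions: 4 AND gates (and1-and4), 4 NOT inputs, 4 OR gates
# (PI3K, MEK12, JNK, P38 each have two producers); 20 free parameters with
# the Hill coefficient fixed.
# The wiring of PI3Ki into the two PI3K-producing gates and of PI3K into AKT
# is inferred from the published network diagram rather than its text; it is
# the unique assignment consistent with the stated gate counts and with AKT
# responding to TNFa while MEK12/ERK12 do not.
TGFa 1 and1
PI3Ki -1 and1
and1 1 PI3K
TNFa 1 and2
PI3Ki -1 and2
and2 1 PI3K
TGFa 1 and3
MEK12i -1 and3
and3 1 MEK12
PI3K 1 and4
MEK12i -1 and4
and4 1 MEK12
MEK12 1 ERK12
PI3K 1 AKT
TNFa 1 JNK
PI3K 1 JNK
TNFa 1 P38
PI3K 1 P38
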