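# Tokens (with trailing period) that never end a sentence.
E.
Fig.
Figs.
al.
et al.
i.e.
e.g.
vs.
cf.
ca.
approx.
Dr.
No.
St.
spp.
sp.
var.
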