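# Interaction-verb lemmas used to flag candidate pairs that enclose a verb
# describing a molecular interaction or regulation. One lemma per line.
activate
inhibit
bind
block
stimulate
suppress
induce
regulate
upregulate
downregulate
increase
decrease
enhance
reduce
mediate
modulate
phosphorylate
dephosphorylate
catalyze
cleave
degrade
stabilize
attenuate
antagonize
potentiate
promote
trigger
abolish
augment
elevate
inactivate
metabolize
oxidize
transport
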