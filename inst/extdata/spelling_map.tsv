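variant	american
colour	color
flavour	flavor
fibre	fiber
behaviour	behavior
sulphur	sulfur
grey	gray
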