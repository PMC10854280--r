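# death-inducing signalling complex rule from the T-LGL leukemia model;
# Ceramide, Fas and FLIP appear only on the right, so they are external
# parameters of this one-node fragment
targets, factors
DISC, Ceramide | (Fas & !FLIP)
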