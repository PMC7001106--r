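# Reference preset: the sampling used for the headline depth-recovery and
# ddG numbers (38 windows x 51000 retained steps; 21 lambda windows).
preset: reference
seed: 1
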