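# Reduced-sampling preset: quick end-to-end runs (seconds to ~2 min).
preset: ci
seed: 1
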