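scale,low_samples,high_samples
valence,1344,1128
arousal,960,1800
dominance,1068,1860
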