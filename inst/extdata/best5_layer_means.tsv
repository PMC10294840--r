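# Reference per-layer mean accuracy rates (20 runs each) for the five
# top-ranked ResNet-18 layers on the 712-image fluorescein corneal-ulcer set:
# GA-selected pipeline (proposed_mean) vs all-maps feed-forward baseline
# (baseline_mean). Used as inputs by the gain and significance examples.
layer	proposed_mean	baseline_mean
res5b_branch2a	0.8582	0.685
bn5b_branch2a	0.8498	0.6862
res5a_branch2a	0.8423	0.6808
res5b_branch2b	0.8359	0.6923
res5a_relu	0.8246	0.6887
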