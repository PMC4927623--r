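muscle,estimate_large_herd,estimate_small_herd,delta,p_adjusted_printed
anterior_deltoid,9.62,8.25,1.37,0.42
upper_trapezius,13.47,8.03,5.44,0.002
biceps_brachii,19.32,6.85,12.47,<0.001
wrist_flexors,12.62,5.63,6.99,<0.001
wrist_extensors,13.90,15.06,-1.16,0.50
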