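group,muscle,metric,mean,sd
large_herd_US,upper_trapezius,apdf_p10,1.13,2.07
large_herd_US,anterior_deltoid,apdf_p10,0.15,0.39
large_herd_US,biceps_brachii,apdf_p10,1.21,2.22
large_herd_US,wrist_flexors,apdf_p10,0.54,0.92
large_herd_US,wrist_extensors,apdf_p10,0.40,0.59
large_herd_US,upper_trapezius,apdf_p50,9.28,6.61
large_herd_US,anterior_deltoid,apdf_p50,3.49,3.71
large_herd_US,biceps_brachii,apdf_p50,14.58,11.5
large_herd_US,wrist_flexors,apdf_p50,7.41,5.10
large_herd_US,wrist_extensors,apdf_p50,9.75,5.70
large_herd_US,upper_trapezius,apdf_p90,31.44,21.04
large_herd_US,anterior_deltoid,apdf_p90,43.36,36.26
large_herd_US,biceps_brachii,apdf_p90,51.22,38.86
large_herd_US,wrist_flexors,apdf_p90,44.11,31.13
large_herd_US,wrist_extensors,apdf_p90,36.74,21.40
large_herd_US,upper_trapezius,mean_rms,0.58,9.19
large_herd_US,anterior_deltoid,mean_rms,9.74,3.71
large_herd_US,biceps_brachii,mean_rms,19.44,13.87
large_herd_US,wrist_flexors,mean_rms,12.73,6.24
large_herd_US,wrist_extensors,mean_rms,14.02,7.73
large_herd_US,upper_trapezius,percent_rest,6.64,7.24
large_herd_US,anterior_deltoid,percent_rest,22.77,12.75
large_herd_US,biceps_brachii,percent_rest,9.45,7.34
large_herd_US,wrist_flexors,percent_rest,13.58,8.25
large_herd_US,wrist_extensors,percent_rest,13.16,6.69
small_herd_IT,upper_trapezius,apdf_p10,0.66,1.18
small_herd_IT,anterior_deltoid,apdf_p10,0.16,0.88
small_herd_IT,biceps_brachii,apdf_p10,0.076,0.69
small_herd_IT,wrist_flexors,apdf_p10,0.15,1.52
small_herd_IT,wrist_extensors,apdf_p10,0.23,1.85
small_herd_IT,upper_trapezius,apdf_p50,6.28,4.29
small_herd_IT,anterior_deltoid,apdf_p50,3.60,3.99
small_herd_IT,biceps_brachii,apdf_p50,4.38,2.73
small_herd_IT,wrist_flexors,apdf_p50,2.51,2.67
small_herd_IT,wrist_extensors,apdf_p50,9.23,5.58
small_herd_IT,upper_trapezius,apdf_p90,19.50,12.27
small_herd_IT,anterior_deltoid,apdf_p90,29.61,24.31
small_herd_IT,biceps_brachii,apdf_p90,19.75,9.94
small_herd_IT,wrist_flexors,apdf_p90,35.85,48.81
small_herd_IT,wrist_extensors,apdf_p90,43.43,36.76
small_herd_IT,upper_trapezius,mean_rms,8.46,5.35
small_herd_IT,anterior_deltoid,mean_rms,8.26,5.23
small_herd_IT,biceps_brachii,mean_rms,6.86,4.02
small_herd_IT,wrist_flexors,mean_rms,5.64,4.12
small_herd_IT,wrist_extensors,mean_rms,14.60,7.78
small_herd_IT,upper_trapezius,percent_rest,0.59,1.22
small_herd_IT,anterior_deltoid,percent_rest,4.98,5.88
small_herd_IT,biceps_brachii,percent_rest,5.36,10.10
small_herd_IT,wrist_flexors,percent_rest,4.67,4.55
small_herd_IT,wrist_extensors,percent_rest,5.67,3.36
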