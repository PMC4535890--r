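het_level: 0.01
bin_width: 0.1
threshold_A: ~
threshold_B: ~
marker_min: 0.9
sample_min: 0.96
freq_tolerance: 0.1
rare_maf: 0.05
maf_min: 0.05
window_bp: 300000.0
r2_threshold: 0.8
alpha: 0.01
n_perm: 10000.0
min_width: 2.0
loss_threshold_A: ~
loss_threshold_B: ~
gain_threshold: 0.5
min_size_bp: 50.0
min_overlap_bp: 1.0
size_corr_min_bp: 10000.0
merge_bookended: yes
master_seed: 1.0
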