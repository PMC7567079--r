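# retvasc pipeline configuration (key = value; unknown keys are an error)
canny_sigma = 1.4
canny_low_quantile = 0.10
canny_high_quantile = 0.30
circular_mask_fraction = none
min_object_px = 30
close_radius = 3
fill_sliver_px = 2
prune_spur_px = 4
min_mesh_px = 300
mesh_scope = master
alpha = 0.05
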