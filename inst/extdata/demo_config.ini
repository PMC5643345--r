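# Demo configuration for the cortexpci pipeline (desk-scale phantom).
# Keys mirror pipeline_config(); see ?pipeline_config for units.
# Geometry rule of thumb: both the medullary cavity radius and the air
# margin around the cortex must exceed the closing radius.

[phantom]
grid_n = 96
voxel_size_um = 1
cortex_outer_radius_um = 34
cortex_inner_radius_um = 14
n_canals = 4
canal_diameter_mean_um = 6
canal_diameter_sd_um = 0.5
canal_orientation_jitter_deg = 2
occupancy_fraction = 0.96
vessel_fill_fraction = 0.85
vessel_wall_thickness_um = 1
lacunar_density_per_mm3 = 40000
lacuna_semi_axes_um = 4.5, 2, 2
seed = 1

[acquisition]
energy_kev = 21
n_projections = 121
photons_per_pixel = Inf
distance_near_mm = 5
distance_phase_mm = 25
psf_fwhm_px = 1

[reconstruction]
fbp_window = none
log_floor = 1e-9

[segmentation]
closing_radius_um = 12
smooth_sigma_vox = 0.8
volume_cutoff_um3 = 2000
elongation_cutoff = 5
min_size_vox = 27
k_sigma = 3
contrast_floor = 1
ring_frac = 0.5
min_extent_vox = 8

[morphometry]
n_slices = 60
dataset_id = demo
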