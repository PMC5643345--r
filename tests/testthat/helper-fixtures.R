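# Shared fixtures. Heavy simulations are memoised in `.sim_cache` so several
# test files can reuse one end-to-end run.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# Small mixed-occupancy phantom world imaged noiselessly at D = 0, 5, 25 mm.
# Used by segmentation, vessel-detection, line-profile and morphometry tests.
small_world <- function() {
  cached("small_world", {
    spec <- phantom_spec(grid_shape = c(48L, 128L, 128L), voxel_size_um = 1,
                         cortex_outer_radius_um = 44, cortex_inner_radius_um = 26,
                         n_canals = 5, canal_diameter_mean_um = 8,
                         canal_diameter_sd_um = 0.7,
                         canal_orientation_jitter_deg = 2,
                         occupancy_fraction = 0.6, vessel_fill_fraction = 0.85,
                         lacunar_density_per_mm3 = 3e4, rng_seed = 42)
    ph <- build_phantom(spec)
    mat <- labels_to_materials(ph)
    proj <- project_complex(mat, beam_config(propagation_mm = 0,
                                             n_projections = 161,
                                             detector_pixel_um = 1))
    recs <- lapply(c(0, 5, 25), function(D) {
      reconstruct_fbp(acquire(mat, beam_config(propagation_mm = D,
                                               n_projections = 161,
                                               detector_pixel_um = 1,
                                               psf_fwhm_px = 1),
                              projections = proj))
    })
    names(recs) <- c("d0", "near", "phase")
    bone <- segment_bone(recs$near, smooth_sigma_vox = 0.8)
    pores <- extract_pores(bone, 24)
    cls <- classify_pores(pores, min_size_vox = 27)
    vessels <- detect_vessels(recs$phase, cls, bone, recon_near = recs$near)
    list(spec = spec, phantom = ph, materials = mat, proj = proj,
         recs = recs, bone = bone, pores = pores, cls = cls,
         vessels = vessels)
  })
}

# Tiny noiseless pipeline configuration used for smoke/determinism tests.
tiny_pipeline_config <- function(out_dir = NULL, ...) {
  pipeline_config(grid_n = 80L, voxel_size_um = 1,
                  cortex_outer_radius_um = 28, cortex_inner_radius_um = 14,
                  n_canals = 2L, canal_diameter_mean_um = 6,
                  canal_diameter_sd_um = 0.4,
                  canal_orientation_jitter_deg = 1,
                  lacunar_density_per_mm3 = 3e4,
                  closing_radius_um = 10, n_projections = 121L,
                  n_slices = 20L, verbose = FALSE, out_dir = out_dir, ...)
}

tiny_pipeline_run <- function() {
  cached("tiny_pipeline_run", run_pipeline(tiny_pipeline_config()))
}

# Directly rasterised solid cylinder along z (no imaging), for morphometry
# oracles. Centre falls on a voxel when n is odd.
digital_cylinder <- function(diameter, n_xy, n_z = 30L) {
  cc <- seq_len(n_xy) - (n_xy + 1) / 2
  disk <- outer(cc^2, cc^2, `+`) <= (diameter / 2)^2
  m <- array(FALSE, dim = c(n_z, n_xy, n_xy))
  for (z in seq_len(n_z)) m[z, , ] <- disk
  m
}

digital_sphere <- function(diameter, n = diameter + 10L) {
  cc <- seq_len(n) - (n + 1) / 2
  q <- outer(outer(cc^2, cc^2, `+`), cc^2, `+`)
  array(q <= (diameter / 2)^2, dim = c(n, n, n))
}

# Exhaustive largest-inscribed-sphere local thickness oracle (<= 64^3):
# for every mask voxel p, max over mask centres c with |p-c| <= r(c) of
# 2 r(c), where r(c) is the Euclidean distance to the nearest background
# voxel centre. Independent of the painting implementation.
brute_local_thickness <- function(mask) {
  nm <- !mask; dim(nm) <- dim(mask)
  r2 <- cortexpci:::cpp_edt_sq(nm, dim(mask))
  idx <- which(mask)
  co <- arrayInd(idx, dim(mask))
  rv <- r2[idx]
  out <- vapply(seq_along(idx), function(i) {
    d2 <- (co[, 1] - co[i, 1])^2 + (co[, 2] - co[i, 2])^2 +
      (co[, 3] - co[i, 3])^2
    2 * sqrt(max(rv[d2 <= rv]))
  }, numeric(1))
  lt <- array(0, dim = dim(mask))
  lt[idx] <- out
  lt
}

# Brute-force two-sided Mann-Whitney p by enumerating all choose(N, n1)
# group labelings of the pooled values (midranks; doubled smaller tail).
brute_mw_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  N <- length(pooled)
  r <- rank(pooled, ties.method = "average")
  u_of <- function(sel) sum(r[sel]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  sets <- utils::combn(N, n1)
  us <- apply(sets, 2, u_of)
  p_lo <- mean(us <= u_obs + 1e-9)
  p_hi <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# Intensity after Fresnel propagation of a 1D phase step exp(i phi0 * (x>0)),
# from the closed form U(x) = (1 - K) + exp(i phi0) K with
# K = [(1/2 + C(w)) + i (1/2 + S(w))] / (1 + i), w = x sqrt(2/(lambda D)),
# where C, S are the Fresnel integrals evaluated by adaptive quadrature on a
# finite smooth interval. Independent oracle for the FFT propagator.
phase_step_intensity <- function(x, phi0, lambda_um, D_um) {
  w <- x * sqrt(2 / (lambda_um * D_um))
  vapply(w, function(wi) {
    C <- stats::integrate(function(u) cos(pi * u^2 / 2), 0, wi,
                          rel.tol = 1e-10)$value
    S <- stats::integrate(function(u) sin(pi * u^2 / 2), 0, wi,
                          rel.tol = 1e-10)$value
    K <- complex(real = 0.5 + C, imaginary = 0.5 + S) / complex(real = 1,
                                                                imaginary = 1)
    Mod((1 - K) + exp(1i * phi0) * K)^2
  }, numeric(1))
}

# Anti-aliased disk: per-voxel coverage fraction of the analytic disk by
# 8 x 8 supersampling, so the rasterised object approximates the analytic
# cylinder to sub-voxel accuracy.
aa_disk <- function(n, R) {
  ss <- 8
  off <- (seq_len(ss) - (ss + 1) / 2) / ss
  cov <- matrix(0, n, n)
  cc <- seq_len(n) - (n + 1) / 2
  for (oy in off) for (ox in off)
    cov <- cov + (outer((cc + oy)^2, (cc + ox)^2, `+`) <= R^2)
  cov / ss^2
}

# Build a minimal recon_volume by hand for tests that bypass the simulator.
fake_recon <- function(values, voxel = 1, distance_mm = 5, psf = 0) {
  structure(list(values = values, voxel_size_um = voxel,
                 provenance = beam_config(propagation_mm = distance_mm,
                                          detector_pixel_um = voxel,
                                          psf_fwhm_px = psf)),
            class = "recon_volume")
}
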