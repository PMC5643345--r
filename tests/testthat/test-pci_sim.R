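test_that("energy/wavelength conversion round-trips to 6 significant figures", {
  for (E in c(8, 21, 30.5)) {
    b <- beam_config(energy_kev = E, propagation_mm = 0)
    expect_equal(b$wavelength_nm, 1.23984193 / E, tolerance = 1e-12)
    expect_equal(1.23984193 / b$wavelength_nm, E, tolerance = 1e-7)
  }
  expect_equal(beam_config(energy_kev = 21)$wavelength_nm, 0.0590401,
               tolerance = 1e-6)
})

test_that("beam_config validates its inputs", {
  expect_error(beam_config(energy_kev = 0), "energy")
  expect_error(beam_config(propagation_mm = -1), "propagation")
  expect_error(beam_config(n_projections = 0), "projections")
  expect_error(beam_config(photons_per_pixel = 0), "photons")
})

test_that("zero material volume projects to unit transmission at all angles", {
  mat <- structure(list(delta_map = array(0, c(4, 16, 16)),
                        beta_map = array(0, c(4, 16, 16)),
                        voxel_size_um = 1, energy_kev = 21),
                   class = "material_volume")
  proj <- project_complex(mat, beam_config(propagation_mm = 0,
                                           n_projections = 7,
                                           detector_pixel_um = 1))
  for (i in 1:7) expect_true(all(abs(transmission_at(proj, i) - 1) < 1e-14))
})

test_that("cylinder phase integrals match the analytic chord length within 2%", {
  n <- 96; R <- 24; delta0 <- 5e-7
  cc <- seq_len(n) - (n + 1) / 2
  disk <- aa_disk(n, R)   # anti-aliased: the object is the analytic cylinder
  dm <- array(0, c(2, n, n)); for (z in 1:2) dm[z, , ] <- disk * delta0
  mat <- structure(list(delta_map = dm, beta_map = array(0, c(2, n, n)),
                        voxel_size_um = 1, energy_kev = 21),
                   class = "material_volume")
  beam <- beam_config(propagation_mm = 0, n_projections = 4,
                      detector_pixel_um = 1)
  proj <- project_complex(mat, beam)
  lambda_um <- beam$wavelength_nm * 1e-3
  t <- (seq_len(n) - (n + 1) / 2)   # detector offsets in um
  inner <- abs(t) <= R - 2          # rays at least 2 voxels from the rim
  expected <- (2 * pi / lambda_um) * delta0 * 2 * sqrt(pmax(R^2 - t^2, 0))
  for (i in seq_along(proj$angles)) {
    got <- abs(proj$phi[1, , i])
    expect_lt(max(abs(got[inner] - expected[inner]) / expected[inner]), 0.02)
  }
})

test_that("projection of a y-mirrored volume equals the t-mirrored projection at pi - theta", {
  set.seed(10)
  vol <- array(runif(4 * 32 * 32), c(4, 32, 32))
  vol[, 1:4, ] <- 0; vol[, 29:32, ] <- 0; vol[, , 1:4] <- 0; vol[, , 29:32] <- 0
  mirr <- vol[, rev(seq_len(32)), , drop = FALSE]
  angles <- c(0.3, 1.1)
  p <- cortexpci:::cpp_radon(vol, dim(vol), pi - angles)
  pm <- cortexpci:::cpp_radon(mirr, dim(mirr), angles)
  for (i in seq_along(angles))
    expect_equal(pm[, , i], p[, rev(seq_len(32)), i], tolerance = 1e-10)
})

test_that("Fresnel propagation at distance 0 is the exact identity", {
  set.seed(4)
  tr <- matrix(complex(real = runif(64^2), imaginary = runif(64^2)), 64, 64)
  expect_equal(fresnel_propagate(tr, 0, 0.059, 1), Mod(tr)^2, tolerance = 0)
})

test_that("a spatially uniform phase plane propagates to unit intensity", {
  tr <- matrix(exp(1i * 0.7), 48, 48)
  out <- fresnel_propagate(tr, 25, 0.0590401, 1)
  expect_lt(max(abs(out - 1)), 1e-12)
})

test_that("phase-edge fringe position matches a direct Fresnel integral oracle", {
  lambda_um <- 0.0590401 * 1e-3
  D_um <- 25e3
  px <- 0.1
  n <- 2048
  x <- (seq_len(n) - n / 2) * px
  phi0 <- 0.5
  tr <- matrix(exp(1i * phi0 * (x > 0)), 1, n)
  I <- fresnel_propagate(tr, 25, 0.0590401, px)[1, ]
  # first intensity maximum on the positive side, away from the edge pixel
  side <- which(x > 0.15 & x < 6)
  pk_impl <- x[side][which.max(I[side])]

  xs <- seq(0.2, 6, by = 0.02)
  Uo <- phase_step_intensity(xs, phi0, lambda_um, D_um)
  pk_oracle <- xs[which.max(Uo)]
  expect_lt(abs(pk_impl - pk_oracle) / pk_oracle, 0.10)
  # and the propagated field matches the oracle pointwise on the detector
  # grid; the sampled step (x > 0) has its effective edge half a pixel from
  # the analytic step, so the oracle is evaluated at x - px/2
  xg <- seq(0.2, 6, by = 0.1)
  expect_lt(max(abs(I[match(round(xg, 4), round(x, 4))] -
                    phase_step_intensity(xg - px / 2, phi0, lambda_um, D_um))),
            0.02)
  # the fringe sits at the sqrt(lambda D) scale (~1.2 um)
  expect_gt(pk_impl, 0.3 * sqrt(lambda_um * D_um))
  expect_lt(pk_impl, 2.0 * sqrt(lambda_um * D_um))
})

test_that("contact-plane absorption sinogram equals the mu line integrals", {
  w <- small_world()
  mat <- w$materials
  mat$delta_map[] <- 0
  beam <- beam_config(propagation_mm = 0, n_projections = 21,
                      detector_pixel_um = 1)
  proj <- project_complex(mat, beam)
  sino <- acquire(mat, beam)
  expect_lt(max(abs(-log(sino$intensities) - proj$mu)), 1e-6)
})

test_that("noiseless acquisition is deterministic; Poisson noise is seeded and unbiased", {
  mat <- structure(list(delta_map = array(0, c(1, 24, 24)),
                        beta_map = array(0, c(1, 24, 24)),
                        voxel_size_um = 1, energy_kev = 21),
                   class = "material_volume")
  beam <- beam_config(propagation_mm = 0, n_projections = 3,
                      detector_pixel_um = 1)
  expect_identical(acquire(mat, beam)$intensities,
                   acquire(mat, beam)$intensities)
  nb <- beam_config(propagation_mm = 0, n_projections = 3,
                    detector_pixel_um = 1, photons_per_pixel = 1000,
                    rng_seed = 77)
  s1 <- acquire(mat, nb); s2 <- acquire(mat, nb)
  expect_identical(s1$intensities, s2$intensities)
  # mean of one background pixel over 100 independent draws: 1 within 3 SE
  draws <- vapply(1:100, function(s) {
    b <- beam_config(propagation_mm = 0, n_projections = 1,
                     detector_pixel_um = 1, photons_per_pixel = 1000,
                     rng_seed = s)
    acquire(mat, b)$intensities[1, 12, 1]
  }, numeric(1))
  se <- sqrt(1 / 1000 / 100)
  expect_lt(abs(mean(draws) - 1), 3 * se)
})

test_that("ring correction is a no-op on clean data and fixes a gain defect", {
  w <- small_world()
  beam <- beam_config(propagation_mm = 0, n_projections = 41,
                      detector_pixel_um = 1)
  sino <- acquire(w$materials, beam)
  clean <- ring_correct(sino)
  expect_lt(max(abs(clean$intensities - sino$intensities)), 1e-6)

  bad <- sino
  col <- 60
  bad$intensities[, col, ] <- bad$intensities[, col, ] * 1.1
  fixed <- ring_correct(bad)
  m <- apply(log(fixed$intensities[25, , ]), 1, mean)
  neigh <- (m[col - 1] + m[col + 1]) / 2
  expect_lt(abs(m[col] - neigh), 0.01)

  zero <- sino; zero$intensities[] <- 0
  expect_true(all(ring_correct(zero)$intensities == 0))

  few <- sino; few$intensities <- few$intensities[, , 1:4, drop = FALSE]
  expect_error(ring_correct(few), ">= 8 angles")
})

test_that("FBP of a uniform unit sinogram is zero and the map is linear", {
  beam <- beam_config(propagation_mm = 0, n_projections = 31,
                      detector_pixel_um = 1)
  sino <- structure(list(intensities = array(1, c(4, 32, 31)),
                         angles = projection_angles(beam), beam = beam),
                    class = "sinogram")
  rec <- reconstruct_fbp(sino)
  expect_lt(max(abs(rec$values)), 1e-6)
  expect_identical(dim(rec$values), c(4L, 32L, 32L))

  set.seed(6)
  p <- array(runif(4 * 32 * 31, 0.5, 1), c(4, 32, 31))
  s1 <- sino; s1$intensities <- p
  s2 <- sino; s2$intensities <- p^2.5   # -log scales by 2.5
  r1 <- reconstruct_fbp(s1); r2 <- reconstruct_fbp(s2)
  expect_equal(r2$values, 2.5 * r1$values, tolerance = 1e-10)

  one <- sino; one$intensities <- one$intensities[, , 1, drop = FALSE]
  one$angles <- one$angles[1]
  expect_error(reconstruct_fbp(one), ">= 2 angles")
})

test_that("FBP reconstructs an absorption disk quantitatively", {
  n <- 48; R <- 15; mu_vox <- 4e-4
  cc <- seq_len(n) - (n + 1) / 2
  disk <- outer(cc^2, cc^2, `+`) <= R^2
  lam <- 1.23984193 / 21 * 1e-3
  bm <- array(0, c(2, n, n))
  for (z in 1:2) bm[z, , ] <- disk * (mu_vox * lam / (4 * pi))
  mat <- structure(list(delta_map = array(0, c(2, n, n)), beta_map = bm,
                        voxel_size_um = 1, energy_kev = 21),
                   class = "material_volume")
  rec <- reconstruct_fbp(acquire(mat, beam_config(propagation_mm = 0,
                                                  n_projections = 121,
                                                  detector_pixel_um = 1)))
  truth <- disk * mu_vox
  rr <- outer(cc^2, cc^2, `+`)
  sel <- rr <= (R - 2)^2 | rr >= (R + 2)^2
  err <- rec$values[1, , ] - truth
  expect_lt(sqrt(mean(err[sel]^2)) / mu_vox, 0.05)
})

test_that("a centred point source reconstructs with its argmax at the true location", {
  n <- 33
  lam <- 1.23984193 / 21 * 1e-3
  bm <- array(0, c(1, n, n))
  bm[1, 17, 17] <- 1e-4 * lam / (4 * pi)
  mat <- structure(list(delta_map = array(0, c(1, n, n)), beta_map = bm,
                        voxel_size_um = 1, energy_kev = 21),
                   class = "material_volume")
  rec <- reconstruct_fbp(acquire(mat, beam_config(propagation_mm = 0,
                                                  n_projections = 45,
                                                  detector_pixel_um = 1)))
  expect_identical(as.integer(which.max(rec$values[1, , ])),
                   as.integer((17 - 1) * n + 17))
})

test_that("two propagation distances share the identical projection stage", {
  w <- small_world()
  b1 <- beam_config(propagation_mm = 5, n_projections = 161,
                    detector_pixel_um = 1, psf_fwhm_px = 1)
  direct <- acquire(w$materials, b1)
  via_proj <- acquire(w$materials, b1, projections = w$proj)
  expect_equal(direct$intensities, via_proj$intensities, tolerance = 1e-12)
})

test_that("the transfer-function sampling bound triggers a warning", {
  tr <- matrix(complex(real = 1, imaginary = 0), 16, 16)
  expect_warning(fresnel_propagate(tr, 500, 0.059, 0.5), "aliased")
})
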