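test_that("Otsu threshold separates a two-value volume exactly and rejects constants", {
  set.seed(2)
  x <- c(rep(0, 4000), rep(1, 2500))
  thr <- otsu_threshold(x)
  expect_gt(thr, 0); expect_lt(thr, 1)
  expect_error(otsu_threshold(rep(3.3, 100)), "degenerate")
})

test_that("segment_bone recovers a noiseless two-value volume exactly", {
  vals <- array(0, c(8, 40, 40))
  cc <- seq_len(40) - 20.5
  ring <- outer(cc^2, cc^2, `+`) <= 15^2 & outer(cc^2, cc^2, `+`) >= 6^2
  for (z in 1:8) vals[z, , ] <- ring * 1.0
  rec <- fake_recon(vals)
  b <- segment_bone(rec, smooth_sigma_vox = 0, regularize_sigma_vox = 0)
  expect_identical(b$mask, array(vals > 0.5, dim(vals)))
  expect_error(segment_bone(fake_recon(array(1, c(4, 8, 8)))), "degenerate")
})

test_that("bone segmentation of a simulated scan overlaps the true labels", {
  w <- small_world()
  truth <- array(w$phantom$labels == 1L, dim(w$phantom$labels))
  dice <- 2 * sum(w$bone$mask & truth) / (sum(w$bone$mask) + sum(truth))
  expect_gt(dice, 0.95)
})

test_that("pore extraction is the negative imprint of the mineralised tissue", {
  ph <- build_phantom(phantom_spec(grid_shape = c(16L, 96L, 96L),
                                   voxel_size_um = 1,
                                   cortex_outer_radius_um = 34,
                                   cortex_inner_radius_um = 14,
                                   n_canals = 1, canal_diameter_mean_um = 8,
                                   canal_diameter_sd_um = 1e-9,
                                   canal_orientation_jitter_deg = 0,
                                   lacunar_density_per_mm3 = 0, rng_seed = 4))
  bone <- structure(list(mask = array(ph$labels == 1L, dim(ph$labels)),
                         voxel_size_um = 1, threshold_used = NA_real_),
                    class = "bone_mask")
  po <- extract_pores(bone, 12)
  expect_identical(po$pores, array(ph$labels %in% 2:4, dim(ph$labels)))
  # closing radius 0 is the identity: no pores
  expect_false(any(extract_pores(bone, 0)$pores))
  # solid cortex has no pores
  solid <- bone
  solid$mask[ph$labels %in% 2:4] <- TRUE
  expect_false(any(extract_pores(solid, 12)$pores))
  expect_error(extract_pores(structure(list(mask = array(FALSE, c(2, 2, 2)),
                                            voxel_size_um = 1),
                                       class = "bone_mask"), 5), "empty")
})

test_that("canal/lacuna classification is fully correct on noiseless labels", {
  ph <- build_phantom(phantom_spec(grid_shape = c(120L, 128L, 128L),
                                   voxel_size_um = 1,
                                   cortex_outer_radius_um = 48,
                                   cortex_inner_radius_um = 24,
                                   n_canals = 10, lacunar_density_per_mm3 = 2e5,
                                   canal_orientation_jitter_deg = 2,
                                   rng_seed = 12))
  pores <- array(ph$labels %in% 2:5, dim(ph$labels))
  cls <- classify_pores(pores, voxel_size_um = 1)
  truecanal <- ph$labels %in% 2:4
  expect_gt(sum(cls$components$class == "lacuna"), 100)
  expect_identical(sum(cls$components$class == "canal"), 10L)
  for (i in seq_len(nrow(cls$components))) {
    sel <- cls$labels == cls$components$id[i]
    truth <- if (any(truecanal[sel])) "canal" else "lacuna"
    expect_identical(cls$components$class[i], truth)
  }
})

test_that("classification edge cases: single voxel, empty volume, speckle filter", {
  m <- array(FALSE, c(8, 8, 8)); m[4, 4, 4] <- TRUE
  cls <- classify_pores(m, voxel_size_um = 1)
  expect_identical(cls$components$class, "lacuna")
  expect_equal(cls$components$elongation, 1, tolerance = 1e-9)

  empty <- classify_pores(array(FALSE, c(4, 4, 4)), voxel_size_um = 1)
  expect_identical(nrow(empty$components), 0L)

  two <- array(FALSE, c(8, 12, 12))
  two[4, 2:3, 2] <- TRUE             # 2-voxel speckle
  two[2:7, 8:10, 8:10] <- TRUE       # 54-voxel blob
  cls2 <- classify_pores(two, voxel_size_um = 1, min_size_vox = 10)
  expect_identical(nrow(cls2$components), 1L)
  expect_identical(cls2$components$n_voxels, 54L)
})

test_that("classification is invariant to axis permutation", {
  w <- small_world()
  pores <- w$pores$pores
  base <- classify_pores(pores, voxel_size_um = 1)
  perm <- classify_pores(aperm(pores, c(3, 1, 2)), voxel_size_um = 1)
  key <- function(cls) {
    o <- order(cls$components$n_voxels, cls$components$elongation)
    cbind(cls$components$n_voxels[o], cls$components$class[o])
  }
  expect_identical(key(perm), key(base))
})

test_that("vessel detection flags match the phantom registry on noiseless data", {
  w <- small_world()
  reg <- w$phantom$registry
  # map each detected canal component to its registry entry by position
  occ <- w$vessels$occupancy
  comp <- w$cls$components
  canal_ids <- comp$id[comp$class == "canal"]
  expect_identical(length(canal_ids), nrow(reg))
  d <- dim(w$cls$labels)
  per_canal <- vapply(canal_ids, function(id) {
    mean(occ$occupied[occ$canal_id == id])
  }, numeric(1))
  # locate each component against the registry via its centroid
  truth <- vapply(canal_ids, function(id) {
    idx <- which(w$cls$labels == id)
    co <- arrayInd(idx, d)
    cy <- mean(co[, 2]) - 1 - (d[2] - 1) / 2
    cx <- mean(co[, 3]) - 1 - (d[3] - 1) / 2
    reg$has_vessel[which.min((reg$y0_um - cy)^2 + (reg$x0_um - cx)^2)]
  }, logical(1))
  expect_identical(per_canal >= 0.5, truth)
  # and the per-slice flags are unanimous on noiseless data
  expect_true(all(per_canal == 1 | per_canal == 0))
})

test_that("no vessels are detected on the contact-plane reconstruction", {
  w <- small_world()
  expect_warning(
    vs0 <- detect_vessels(w$recs$d0, w$cls, w$bone),
    "near-absorption")
  expect_false(any(vs0$occupancy$occupied))
  expect_false(any(vs0$mask))
})

test_that("vessel mask is monotone in k_sigma and confined to canals", {
  w <- small_world()
  masks <- lapply(c(2, 3, 5), function(k)
    detect_vessels(w$recs$phase, w$cls, w$bone, k_sigma = k)$mask)
  expect_true(all(masks[[2]] <= masks[[1]]))
  expect_true(all(masks[[3]] <= masks[[2]]))
  cm <- canal_mask(w$cls)
  expect_true(all(!w$vessels$mask | cm))
})

test_that("line profiles: constant image, degenerate segment, bounds", {
  img <- matrix(2.5, 20, 20)
  lp <- line_profile(img, c(2, 2), c(15, 9), pixel_um = 1)
  expect_true(all(lp$values == 2.5))
  expect_gte(length(lp$values), 2)
  single <- line_profile(img, c(5, 5), c(5, 5))
  expect_identical(length(single$values), 1L)
  expect_error(line_profile(img, c(-1, 0), c(3, 3)), "outside")
})

test_that("profiles across an occupied canal show fringes only at the phase distance", {
  w <- small_world()
  reg <- w$phantom$registry
  i <- which(reg$has_vessel)[1]
  d <- dim(w$phantom$labels)
  cy <- reg$y0_um[i] + (d[2] - 1) / 2
  cx <- reg$x0_um[i] + (d[3] - 1) / 2
  r <- reg$diameter_um[i] / 2 + 6
  p0 <- c(cy - r, cx - r); p1 <- c(cy + r, cx + r)
  floor_amp <- abs(median(w$recs$phase$values[w$bone$mask]))
  lp25 <- line_profile(w$recs$phase$values[d[1] / 2, , ], p0, p1, pixel_um = 1,
                       step_um = 0.5)
  lp0 <- line_profile(w$recs$d0$values[d[1] / 2, , ], p0, p1, pixel_um = 1,
                      step_um = 0.5)
  n25 <- count_fringe_extrema(lp25, floor_amp)
  n0 <- count_fringe_extrema(lp0, floor_amp)
  expect_gte(n25, 4)   # at least two over/undershoot pairs
  expect_identical(n0, 0L)
})
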