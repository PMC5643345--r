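test_that("degenerate phantom: no canals, no lacunae gives a solid annulus", {
  spec <- phantom_spec(grid_shape = c(16L, 48L, 48L), voxel_size_um = 1,
                       cortex_outer_radius_um = 20, cortex_inner_radius_um = 8,
                       n_canals = 0, lacunar_density_per_mm3 = 0, rng_seed = 1)
  ph <- build_phantom(spec)
  expect_identical(nrow(ph$registry), 0L)
  expect_identical(ph$n_lacunae, 0L)
  expect_setequal(unique(as.vector(ph$labels)), c(0L, 1L))
  # annular cross-section, constant along z
  expect_true(all(apply(ph$labels, 1, function(s) identical(s, ph$labels[1, , ]))))
})

test_that("occupancy_fraction 1 forces every registry flag true, 0 forces false", {
  base <- list(grid_shape = c(16L, 64L, 64L), voxel_size_um = 1,
               cortex_outer_radius_um = 28, cortex_inner_radius_um = 10,
               n_canals = 4, lacunar_density_per_mm3 = 0, rng_seed = 3)
  ph1 <- build_phantom(do.call(phantom_spec, c(base, occupancy_fraction = 1)))
  ph0 <- build_phantom(do.call(phantom_spec, c(base, occupancy_fraction = 0)))
  expect_true(all(ph1$registry$has_vessel))
  expect_false(any(ph0$registry$has_vessel))
  expect_true(any(ph1$labels %in% c(3L, 4L)))
  expect_false(any(ph0$labels %in% c(3L, 4L)))
})

test_that("phantom generation is bit-reproducible for a fixed seed", {
  spec <- phantom_spec(grid_shape = c(24L, 72L, 72L), voxel_size_um = 1,
                       cortex_outer_radius_um = 30, cortex_inner_radius_um = 12,
                       n_canals = 6, rng_seed = 7)
  a <- build_phantom(spec)
  b <- build_phantom(spec)
  expect_identical(a$labels, b$labels)
  expect_identical(a$registry, b$registry)
  # and different seeds differ
  spec2 <- phantom_spec(grid_shape = c(24L, 72L, 72L), voxel_size_um = 1,
                        cortex_outer_radius_um = 30, cortex_inner_radius_um = 12,
                        n_canals = 6, rng_seed = 8)
  expect_false(identical(build_phantom(spec2)$labels, a$labels))
})

test_that("label-volume invariants hold on a mixed phantom", {
  ph <- small_world()$phantom
  L <- phantom_labels()
  reg <- ph$registry
  labs <- ph$labels
  d <- dim(labs)
  idx <- which(labs == L[["vessel_wall"]] | labs == L[["vessel_lumen"]])
  co <- arrayInd(idx, d)
  v <- ph$voxel_size_um
  zc <- (co[, 1] - 1) * v - (d[1] - 1) / 2 * v
  yc <- (co[, 2] - 1) * v - (d[2] - 1) / 2 * v
  xc <- (co[, 3] - 1) * v - (d[3] - 1) / 2 * v
  # every vessel voxel lies within some registered vessel-bearing canal tube
  wz <- cos(reg$tilt_deg * pi / 180)
  wy <- sin(reg$tilt_deg * pi / 180) * cos(reg$azimuth_deg * pi / 180)
  wx <- sin(reg$tilt_deg * pi / 180) * sin(reg$azimuth_deg * pi / 180)
  inside_any <- rep(FALSE, length(idx))
  for (i in seq_len(nrow(reg))) {
    if (!reg$has_vessel[i]) next
    dy <- yc - reg$y0_um[i]; dx <- xc - reg$x0_um[i]
    proj <- zc * wz[i] + dy * wy[i] + dx * wx[i]
    d2 <- (zc - proj * wz[i])^2 + (dy - proj * wy[i])^2 + (dx - proj * wx[i])^2
    inside_any <- inside_any | d2 <= (reg$diameter_um[i] / 2)^2 + 1e-9
  }
  expect_true(all(inside_any))
  # lacunae never touch canal/vessel voxels (26-adjacency)
  lac <- array(labs == L[["lacuna"]], d)
  can <- array(labs %in% c(L[["canal_lumen"]], L[["vessel_wall"]],
                           L[["vessel_lumen"]]), d)
  touch <- cortexpci:::cpp_touching_labels(array(as.integer(lac), d), can, d)
  expect_length(touch, 0)
  # registry has_vessel flags consistent with voxel labels per canal
  for (i in seq_len(nrow(reg))) {
    dy <- yc - reg$y0_um[i]; dx <- xc - reg$x0_um[i]
    proj <- zc * wz[i] + dy * wy[i] + dx * wx[i]
    d2 <- (zc - proj * wz[i])^2 + (dy - proj * wy[i])^2 + (dx - proj * wx[i])^2
    has_vox <- any(d2 <= (reg$diameter_um[i] / 2)^2 + 1e-9)
    expect_identical(has_vox, reg$has_vessel[i])
  }
})

test_that("ground-truth indices match an exhaustive voxel-count oracle", {
  spec <- phantom_spec(grid_shape = c(32L, 96L, 96L), voxel_size_um = 1,
                       cortex_outer_radius_um = 36, cortex_inner_radius_um = 14,
                       n_canals = 3, occupancy_fraction = 0.8,
                       lacunar_density_per_mm3 = 4e4, rng_seed = 5)
  ph <- build_phantom(spec)
  gt <- ground_truth_indices(ph)
  labs <- as.vector(ph$labels)
  n_bone <- sum(labs == 1); n_canal <- sum(labs %in% 2:4)
  n_ves <- sum(labs %in% 3:4); n_lac_vox <- sum(labs == 5)
  expect_equal(gt$canal_volume_pct,
               100 * n_canal / (n_bone + n_canal + n_lac_vox))
  expect_equal(gt$canal_occupancy_pct, 100 * mean(ph$registry$has_vessel))
  expect_equal(gt$canal_diameter_um, mean(ph$registry$diameter_um))
  expect_equal(gt$vascular_space_pct, 100 * n_ves / n_canal)
  expect_equal(gt$lacunar_density_per_mm3, ph$n_lacunae / (n_bone * 1e-9))
})

test_that("lacuna count follows round(density x realised bone volume)", {
  spec <- phantom_spec(grid_shape = c(24L, 96L, 96L), voxel_size_um = 1,
                       cortex_outer_radius_um = 36, cortex_inner_radius_um = 14,
                       n_canals = 2, lacunar_density_per_mm3 = 4e4, rng_seed = 9)
  ph <- build_phantom(spec)
  # bone volume before lacuna carving = bone voxels + lacuna voxels
  bone_mm3 <- (sum(ph$labels == 1L) + sum(ph$labels == 5L)) * 1e-9
  expect_identical(ph$n_lacunae, as.integer(round(4e4 * bone_mm3)))
})

test_that("single-canal phantom reports its exact registry diameter", {
  spec <- phantom_spec(grid_shape = c(16L, 64L, 64L), voxel_size_um = 1,
                       cortex_outer_radius_um = 28, cortex_inner_radius_um = 10,
                       n_canals = 1, canal_diameter_sd_um = 1e-9,
                       canal_diameter_mean_um = 8,
                       lacunar_density_per_mm3 = 0, rng_seed = 2)
  gt <- ground_truth_indices(build_phantom(spec))
  expect_equal(gt$canal_diameter_um, 8, tolerance = 1e-6)
})

test_that("occupancy index increases with occupancy_fraction in expectation", {
  mk <- function(frac, seed) {
    spec <- phantom_spec(grid_shape = c(8L, 96L, 96L), voxel_size_um = 1,
                         cortex_outer_radius_um = 38,
                         cortex_inner_radius_um = 12, n_canals = 12,
                         canal_orientation_jitter_deg = 0.5,
                         lacunar_density_per_mm3 = 0, rng_seed = seed,
                         occupancy_fraction = frac)
    mean(build_phantom(spec)$registry$has_vessel)
  }
  lo <- mean(vapply(1:6, function(s) mk(0.25, s), numeric(1)))
  hi <- mean(vapply(1:6, function(s) mk(0.85, s), numeric(1)))
  expect_gt(hi, lo)
})

test_that("invalid specifications are rejected", {
  expect_error(phantom_spec(cortex_inner_radius_um = 120,
                            cortex_outer_radius_um = 100), "inner_radius")
  expect_error(phantom_spec(occupancy_fraction = 1.2), "occupancy")
  expect_error(phantom_spec(grid_shape = c(32L, 32L, 32L),
                            cortex_outer_radius_um = 100), "fit the grid")
  expect_error(phantom_spec(canal_diameter_mean_um = 1), "resolvable")
  # geometry that cannot host the requested canal diameter
  expect_error(build_phantom(
    phantom_spec(grid_shape = c(16L, 64L, 64L), cortex_outer_radius_um = 20,
                 cortex_inner_radius_um = 14, n_canals = 1,
                 canal_diameter_mean_um = 8, canal_diameter_sd_um = 1e-9,
                 rng_seed = 1)), "sizing")
})

test_that("ground_truth_indices guards against empty bone", {
  ph <- build_phantom(phantom_spec(grid_shape = c(8L, 32L, 32L),
                                   cortex_outer_radius_um = 12,
                                   cortex_inner_radius_um = 6, n_canals = 0,
                                   lacunar_density_per_mm3 = 0, rng_seed = 1))
  ph$labels[] <- 0L
  expect_error(ground_truth_indices(ph), "no bone")
})

test_that("labels_to_materials is a pure per-voxel lookup", {
  tab <- material_table()
  ph <- build_phantom(phantom_spec(grid_shape = c(8L, 32L, 32L),
                                   cortex_outer_radius_um = 12,
                                   cortex_inner_radius_um = 5, n_canals = 0,
                                   lacunar_density_per_mm3 = 0, rng_seed = 1))
  mat <- labels_to_materials(ph, tab)
  expect_identical(dim(mat$delta_map), dim(ph$labels))
  bone_delta <- tab$delta[tab$name == "bone"]
  expect_true(all(mat$delta_map[ph$labels == 1L] == bone_delta))
  expect_true(all(mat$delta_map[ph$labels == 0L] == 0))
  expect_identical(length(unique(as.vector(mat$beta_map))), 2L)
  # all-background phantom: zero maps
  ph0 <- ph; ph0$labels[] <- 0L
  mat0 <- labels_to_materials(ph0, tab)
  expect_true(all(mat0$delta_map == 0) && all(mat0$beta_map == 0))
  # missing label code errors
  bad <- tab[tab$name != "bone", ]
  class(bad) <- class(tab); attr(bad, "energy_kev") <- 21
  expect_error(labels_to_materials(ph, bad), "missing")
})

test_that("material table validates physical ordering", {
  expect_error(material_table(delta = c(bone = 1e-9)), "exceed")
  expect_error(material_table(beta = c(vessel_wall = -1)), "non-negative")
  tab <- material_table()
  expect_true(all(tab$delta >= 0) && all(tab$beta >= 0))
  expect_identical(tab$delta[tab$name == "background"], 0)
})
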