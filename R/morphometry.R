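new_morphometry_indices <- function(canal_volume_pct, canal_diameter_um,
                                    lacunar_density_per_mm3,
                                    canal_occupancy_pct, vascular_space_pct,
                                    n_slices_sampled, dataset_id) {
  structure(list(canal_volume_pct = canal_volume_pct,
                 canal_diameter_um = canal_diameter_um,
                 lacunar_density_per_mm3 = lacunar_density_per_mm3,
                 canal_occupancy_pct = canal_occupancy_pct,
                 vascular_space_pct = vascular_space_pct,
                 n_slices_sampled = as.integer(n_slices_sampled),
                 dataset_id = dataset_id),
            class = "morphometry_indices")
}

#' @export
print.morphometry_indices <- function(x, ...) {
  cat(sprintf("<morphometry_indices> [%s]\n", x$dataset_id))
  cat(sprintf("  Canal Volume (%%)              %8.3f\n", x$canal_volume_pct))
  cat(sprintf("  Canal Diameter (um)           %8.3f\n", x$canal_diameter_um))
  cat(sprintf("  Canal Occupancy (%%)           %8.3f\n", x$canal_occupancy_pct))
  cat(sprintf("  Vascular Space (%%)            %8.3f\n", x$vascular_space_pct))
  cat(sprintf("  Osteocyte Lacunae (#/mm3)     %8.1f\n", x$lacunar_density_per_mm3))
  cat(sprintf("  (occupancy/space over %d slices)\n", x$n_slices_sampled))
  invisible(x)
}

#' @export
as.data.frame.morphometry_indices <- function(x, ...) {
  data.frame(dataset_id = x$dataset_id,
             canal_volume_pct = x$canal_volume_pct,
             canal_diameter_um = x$canal_diameter_um,
             lacunar_density_per_mm3 = x$lacunar_density_per_mm3,
             canal_occupancy_pct = x$canal_occupancy_pct,
             vascular_space_pct = x$vascular_space_pct,
             n_slices_sampled = x$n_slices_sampled,
             stringsAsFactors = FALSE)
}

#' Canal volume density (%)
#'
#' Canal-class voxels (including any enclosed vessel voxels) as a percentage
#' of the total cortical tissue volume (bone plus all pores).
#'
#' @param classification A `pore_classification`.
#' @param bone A `bone_mask` with matching voxel size.
#' @return Percentage in [0, 100].
#' @export
canal_volume_density <- function(classification, bone) {
  stopifnot(inherits(classification, "pore_classification"),
            inherits(bone, "bone_mask"))
  if (abs(classification$voxel_size_um - bone$voxel_size_um) > 1e-9)
    stopf("canal_volume_density: inconsistent voxel sizes")
  n_canal <- sum(canal_mask(classification))
  n_cortical <- sum(bone$mask) + sum(classification$labels > 0L)
  if (n_cortical == 0) stopf("canal_volume_density: zero cortical volume")
  100 * n_canal / n_cortical
}

#' Mean canal diameter (um) by 3D local thickness
#'
#' Model-independent local thickness: for every canal voxel, the diameter of
#' the largest inscribed sphere containing it (Euclidean distance transform
#' with sphere painting), averaged over canal voxels.
#'
#' @param classification A `pore_classification` with at least one canal.
#' @return Mean diameter in um.
#' @export
mean_canal_diameter <- function(classification) {
  stopifnot(inherits(classification, "pore_classification"))
  m <- canal_mask(classification)
  if (!any(m)) stopf("mean_canal_diameter: no canal components")
  mean(local_thickness(m)[m]) * classification$voxel_size_um
}

#' Local thickness of a binary structure
#'
#' Diameter (voxel units) of the largest sphere containing each voxel while
#' fitting inside the structure, via the EDT ridge / sphere painting scheme.
#'
#' @param mask Logical 3D array.
#' @return Numeric 3D array; 0 outside the mask.
#' @export
local_thickness <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  nm <- !mask
  dim(nm) <- dim(mask)
  # sphere radius at a voxel = Euclidean distance to the nearest background
  # voxel centre (Hildebrand-style); thickness = diameter of the largest
  # such sphere containing the voxel
  d2 <- cpp_edt_sq(nm, dim(mask))
  dim(d2) <- dim(mask)
  cpp_local_thickness(d2, mask, dim(mask))
}

#' Osteocyte lacunar density (count per mm3 of mineralised bone)
#'
#' @param classification A `pore_classification`.
#' @param bone A `bone_mask`.
#' @return Lacuna component count divided by the mineralised bone volume.
#' @export
lacunar_density <- function(classification, bone) {
  stopifnot(inherits(classification, "pore_classification"),
            inherits(bone, "bone_mask"))
  vol_mm3 <- sum(bone$mask) * (bone$voxel_size_um * 1e-3)^3
  if (vol_mm3 <= 0) stopf("lacunar_density: zero bone volume")
  sum(classification$components$class == "lacuna") / vol_mm3
}

sample_slices <- function(classification, n_slices) {
  labs <- classification$labels
  ids <- classification$components$id[classification$components$class == "canal"]
  has_canal <- vapply(seq_len(dim(labs)[1]),
                      function(z) any(labs[z, , ] %in% ids), logical(1))
  zs <- which(has_canal)
  if (!length(zs)) stopf("no canal cross-sections in the volume")
  unique(round(seq(min(zs), max(zs), length.out = min(n_slices, length(zs)))))
}

#' Canal occupancy (%)
#'
#' On `n_slices` evenly spaced slices spanning the cortical canal extent,
#' each canal cross-section (a canal component present in a slice) counts as
#' occupied when at least one vessel voxel of that component lies in the
#' slice. Occupancy is occupied / total cross-sections x 100.
#'
#' @param classification A `pore_classification`.
#' @param vessels A `vessel_mask`.
#' @param n_slices Number of slices inspected (default 60).
#' @return Percentage in [0, 100].
#' @export
canal_occupancy <- function(classification, vessels, n_slices = 60L) {
  stopifnot(inherits(classification, "pore_classification"),
            inherits(vessels, "vessel_mask"))
  if (n_slices < 1L) stopf("canal_occupancy: n_slices must be >= 1")
  labs <- classification$labels
  ids <- classification$components$id[classification$components$class == "canal"]
  zs <- sample_slices(classification, n_slices)
  total <- 0L; occupied <- 0L
  for (z in zs) {
    lslice <- labs[z, , ]
    vslice <- vessels$mask[z, , ]
    pres <- intersect(unique(as.vector(lslice)), ids)
    for (id in pres) {
      total <- total + 1L
      if (any(vslice[lslice == id])) occupied <- occupied + 1L
    }
  }
  if (total == 0L) stopf("canal_occupancy: no canal cross-sections in sampled slices")
  100 * occupied / total
}

#' Vascular space (%)
#'
#' Vessel voxel area as a percentage of canal voxel area over the sampled
#' slices.
#'
#' @inheritParams canal_occupancy
#' @return Percentage in [0, 100].
#' @export
vascular_space <- function(classification, vessels, n_slices = 60L) {
  stopifnot(inherits(classification, "pore_classification"),
            inherits(vessels, "vessel_mask"))
  if (n_slices < 1L) stopf("vascular_space: n_slices must be >= 1")
  cm <- canal_mask(classification)
  zs <- sample_slices(classification, n_slices)
  n_can <- 0; n_ves <- 0
  for (z in zs) {
    cs <- cm[z, , ]
    n_can <- n_can + sum(cs)
    n_ves <- n_ves + sum(vessels$mask[z, , ] & cs)
  }
  if (n_can == 0) stopf("vascular_space: zero canal area in sampled slices")
  100 * n_ves / n_can
}

#' All five morphometric indices from segmentation outputs
#'
#' @param classification A `pore_classification`.
#' @param bone A `bone_mask`.
#' @param vessels A `vessel_mask`.
#' @param n_slices Slices inspected for occupancy/vascular space (default 60).
#' @param dataset_id Label carried into reports.
#' @return A `morphometry_indices` object.
#' @export
morphometry_indices <- function(classification, bone, vessels,
                                n_slices = 60L, dataset_id = "dataset") {
  new_morphometry_indices(
    canal_volume_pct = canal_volume_density(classification, bone),
    canal_diameter_um = mean_canal_diameter(classification),
    lacunar_density_per_mm3 = lacunar_density(classification, bone),
    canal_occupancy_pct = canal_occupancy(classification, vessels, n_slices),
    vascular_space_pct = vascular_space(classification, vessels, n_slices),
    n_slices_sampled = n_slices,
    dataset_id = dataset_id)
}
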