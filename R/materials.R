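#' Phantom label codes
#'
#' Integer codes used in [build_phantom()] label volumes. Background (air) is
#' 0, mineralised bone 1, intracortical canal lumen 2, vessel wall 3, vessel
#' lumen 4 and osteocyte lacuna 5.
#'
#' @return Named integer vector of label codes.
#' @export
phantom_labels <- function() {
  c(background = 0L, bone = 1L, canal_lumen = 2L, vessel_wall = 3L,
    vessel_lumen = 4L, lacuna = 5L)
}

#' Complex refractive index table for the phantom tissue classes
#'
#' Per-label decrement \eqn{\delta} and absorption index \eqn{\beta} of the
#' X-ray refractive index \eqn{n = 1 - \delta + i\beta} at the working photon
#' energy. The defaults are literature-style values at 21 keV computed from
#' \eqn{\delta = r_e \lambda^2 \rho_e / 2\pi} with tabulated electron
#' densities, and \eqn{\beta = \mu \lambda / 4\pi} with standard attenuation
#' coefficients: mineralised cortical bone (density ~2.0 g/cm3); air for the
#' free canal space (fixed, ethanol-stored, unperfused specimens are mounted
#' and scanned in air, and the open canal network drains/dries, which is
#' what gives the soft-tissue vessel its strong edge fringe); soft tissue
#' for the vessel wall; aqueous intravascular fluid in the vessel lumen;
#' osteocyte/interstitial fluid in lacunae; air as background.
#'
#' @param energy_kev Photon energy in keV. Only 21 keV defaults ship; other
#'   energies require explicit `delta`/`beta` overrides.
#' @param delta,beta Optional named numeric vectors overriding individual
#'   labels (names from [phantom_labels()]).
#' @return An object of class `material_table`: data.frame with columns
#'   `label`, `name`, `delta`, `beta`, plus an `energy_kev` attribute.
#' @export
material_table <- function(energy_kev = 21, delta = NULL, beta = NULL) {
  lab <- phantom_labels()
  tab <- data.frame(
    label = unname(lab),
    name  = names(lab),
    delta = c(0,       9.8e-07, 0,       5.5e-07, 5.2e-07, 5.2e-07),
    beta  = c(0,       1.8e-09, 0,       3.5e-10, 3.4e-10, 3.4e-10),
    stringsAsFactors = FALSE
  )
  for (nm in names(delta)) tab$delta[tab$name == nm] <- delta[[nm]]
  for (nm in names(beta))  tab$beta[tab$name == nm]  <- beta[[nm]]
  if (any(tab$delta < 0) || any(tab$beta < 0))
    stopf("material_table: delta and beta must be non-negative")
  if (tab$delta[tab$name == "bone"] <= max(tab$delta[tab$name %in% c("vessel_wall", "canal_lumen")]) ||
      tab$beta[tab$name == "bone"] <= max(tab$beta[tab$name %in% c("vessel_wall", "canal_lumen")]))
    stopf("material_table: bone delta/beta must exceed soft-tissue values")
  attr(tab, "energy_kev") <- energy_kev
  class(tab) <- c("material_table", "data.frame")
  tab
}

#' Map a labelled phantom to delta/beta volumes
#'
#' Pure per-voxel lookup of the complex refractive index from a
#' [material_table()].
#'
#' @param phantom A `labelled_phantom` from [build_phantom()].
#' @param table A `material_table`.
#' @return Object of class `material_volume`: list with `delta_map` and
#'   `beta_map` (3D arrays congruent with the labels), `voxel_size_um` and
#'   `energy_kev`.
#' @export
labels_to_materials <- function(phantom, table = material_table()) {
  stopifnot(inherits(phantom, "labelled_phantom"))
  labs <- sort(unique(as.integer(phantom$labels)))
  missing <- setdiff(labs, table$label)
  if (length(missing))
    stopf("labels_to_materials: label code(s) %s missing from material table",
          paste(missing, collapse = ", "))
  idx <- match(as.integer(phantom$labels), table$label)
  dm <- table$delta[idx]; bm <- table$beta[idx]
  dim(dm) <- dim(phantom$labels); dim(bm) <- dim(phantom$labels)
  structure(list(delta_map = dm, beta_map = bm,
                 voxel_size_um = phantom$voxel_size_um,
                 energy_kev = attr(table, "energy_kev")),
            class = "material_volume")
}

#' @export
print.material_volume <- function(x, ...) {
  cat(sprintf("<material_volume> %s voxels, %.3g um voxel, %g keV\n",
              paste(dim(x$delta_map), collapse = "x"), x$voxel_size_um,
              x$energy_kev))
  invisible(x)
}
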