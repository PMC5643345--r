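#' @useDynLib cortexpci, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rpois rbinom runif rnorm qnorm pnorm sd mad fft mvfft density
#' @importFrom utils write.csv read.csv
NULL

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never clobber user state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Morphology on logical volumes via the exact Euclidean distance transform.
# Radii are in voxel units; a ball of radius 0 is the identity.
dilate_ball <- function(mask, radius_vox) {
  if (radius_vox <= 0) return(mask)
  d2 <- cpp_edt_sq(mask, dim(mask))
  out <- d2 <= radius_vox^2
  dim(out) <- dim(mask)
  out
}

erode_ball <- function(mask, radius_vox) {
  if (radius_vox <= 0) return(mask)
  d2 <- cpp_edt_sq(!mask, dim(mask))
  out <- d2 > radius_vox^2
  dim(out) <- dim(mask)
  out
}

close_ball <- function(mask, radius_vox) {
  erode_ball(dilate_ball(mask, radius_vox), radius_vox)
}

# Isotropic 3D Gaussian smoothing via the frequency-domain OTF; sigma in
# voxels. Used to regularise reconstructions before histogram thresholding.
gaussian_blur3d <- function(vol, sigma_vox) {
  if (sigma_vox <= 0) return(vol)
  d <- dim(vol)
  fz <- fft_freq(d[1], 1); fy <- fft_freq(d[2], 1); fx <- fft_freq(d[3], 1)
  H <- exp(-2 * pi^2 * sigma_vox^2 *
             outer(outer(fz^2, fy^2, `+`), fx^2, `+`))
  out <- Re(fft(fft(vol) * H, inverse = TRUE)) / length(vol)
  dim(out) <- d
  out
}

# Histogram mode via a kernel density estimate: a fringe-robust location
# estimate for the bone attenuation level (interference residue lives in
# the tails of the distribution, so the peak stays at the clean value even
# when a large fraction of voxels is contaminated).
density_mode <- function(x) {
  d <- stats::density(x, n = 512)
  d$x[which.max(d$y)]
}

# Per-stage timing log used by the pipeline and simulator.
log_stage <- function(verbose, stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- force(expr)
  if (isTRUE(verbose))
    message(sprintf("[cortexpci] %-22s %7.2f s", stage, proc.time()[["elapsed"]] - t0))
  res
}
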