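#' Acquisition geometry and beam settings
#'
#' Parallel-beam, fully coherent, monochromatic model of a synchrotron
#' propagation-based imaging setup. The wavelength is derived from the photon
#' energy as \eqn{\lambda[nm] = 1.23984193 / E[keV]}.
#'
#' @param energy_kev Photon energy, keV (default 21).
#' @param propagation_mm Sample-to-detector distance, mm (0 = contact plane).
#' @param n_projections Number of projections over 180 degrees.
#' @param detector_pixel_um Detector pixel size, um; must equal the phantom
#'   voxel size.
#' @param photons_per_pixel Expected incident photon count per pixel for
#'   Poisson noise; `Inf` gives a noiseless acquisition.
#' @param psf_fwhm_px Gaussian detector point-spread FWHM in pixels applied
#'   to the recorded intensities (scintillator/partial-coherence blur).
#'   Default 0 (ideal detector); real detector systems resolve ~2-3x the
#'   pixel size.
#' @param rng_seed Integer seed for the noise generator.
#' @return Object of class `beam_config`.
#' @export
beam_config <- function(energy_kev = 21, propagation_mm = 25,
                        n_projections = 201, detector_pixel_um = 1,
                        photons_per_pixel = Inf, psf_fwhm_px = 0,
                        rng_seed = 1L) {
  if (energy_kev <= 0) stopf("beam_config: energy_kev must be > 0")
  if (propagation_mm < 0) stopf("beam_config: propagation_mm must be >= 0")
  if (n_projections < 1) stopf("beam_config: n_projections must be >= 1")
  if (detector_pixel_um <= 0) stopf("beam_config: detector_pixel_um must be > 0")
  if (photons_per_pixel <= 0) stopf("beam_config: photons_per_pixel must be > 0")
  if (psf_fwhm_px < 0) stopf("beam_config: psf_fwhm_px must be >= 0")
  structure(list(energy_kev = energy_kev,
                 wavelength_nm = 1.23984193 / energy_kev,
                 propagation_mm = propagation_mm,
                 n_projections = as.integer(n_projections),
                 detector_pixel_um = detector_pixel_um,
                 photons_per_pixel = photons_per_pixel,
                 psf_fwhm_px = psf_fwhm_px,
                 rng_seed = as.integer(rng_seed)),
            class = "beam_config")
}

#' Projection angles of a beam configuration
#' @param beam A `beam_config`.
#' @return Angles in radians, `n_projections` values evenly covering [0, pi).
#' @export
projection_angles <- function(beam) {
  (seq_len(beam$n_projections) - 1) * pi / beam$n_projections
}

#' Phase and absorption line integrals of a material volume
#'
#' Under the projection approximation, a parallel ray accumulates the phase
#' \eqn{\phi = -(2\pi/\lambda) \int \delta\, ds} and the absorption exponent
#' \eqn{\mu = (2\pi/\lambda) \int 2\beta\, ds}, so the complex transmission of
#' the object is \eqn{T = \exp(-\mu/2 + i\phi)}. Line integrals are computed
#' by in-plane resampling along rotated rays at voxel steps (linear
#' interpolation), the standard rotate-and-sum scheme.
#'
#' @param materials A `material_volume`.
#' @param beam A `beam_config` whose detector pixel equals the voxel size.
#' @return Object of class `projection_set`: list with `phi` and `mu` arrays
#'   of dim (n_z, n_t, n_angles), `angles`, `beam`, `voxel_size_um`. Use
#'   [transmission_at()] for the complex transmission of one projection.
#' @export
project_complex <- function(materials, beam) {
  stopifnot(inherits(materials, "material_volume"), inherits(beam, "beam_config"))
  if (abs(materials$voxel_size_um - beam$detector_pixel_um) >
      1e-9 * materials$voxel_size_um)
    stopf("project_complex: detector pixel (%g um) must equal voxel size (%g um)",
          beam$detector_pixel_um, materials$voxel_size_um)
  angles <- projection_angles(beam)
  v <- materials$voxel_size_um
  lambda_um <- beam$wavelength_nm * 1e-3
  k <- 2 * pi / lambda_um
  d_int <- cpp_radon(materials$delta_map, dim(materials$delta_map), angles) * v
  b_int <- cpp_radon(materials$beta_map, dim(materials$beta_map), angles) * v
  structure(list(phi = -k * d_int, mu = 2 * k * b_int, angles = angles,
                 beam = beam, voxel_size_um = v),
            class = "projection_set")
}

#' Complex transmission image of one projection
#' @param proj A `projection_set`.
#' @param i Projection index.
#' @return Complex matrix (detector rows z x columns t).
#' @export
transmission_at <- function(proj, i) {
  stopifnot(inherits(proj, "projection_set"))
  tr <- exp(complex(real = -proj$mu[, , i] / 2, imaginary = proj$phi[, , i]))
  dim(tr) <- dim(proj$phi)[1:2]
  tr
}

fft_freq <- function(n, d) {
  pos <- 0:floor((n - 1) / 2)
  neg <- if (n >= 2) -(floor(n / 2):1) else integer(0)
  c(pos, neg) / (n * d)
}

fft2 <- function(x) mvfft(t(mvfft(t(x))))
ifft2 <- function(x) mvfft(t(mvfft(t(x), inverse = TRUE)), inverse = TRUE) / length(x)

# Gaussian blur of a real image by frequency-domain multiplication with the
# Gaussian OTF exp(-2 pi^2 sigma^2 |f|^2); sigma in pixels.
gaussian_blur2d <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  f1 <- fft_freq(nrow(img), 1)
  f2 <- fft_freq(ncol(img), 1)
  H <- exp(-2 * pi^2 * sigma_px^2 * outer(f1^2, f2^2, `+`))
  Re(ifft2(fft2(img) * H))
}

#' Fresnel free-space propagation of a coherent field
#'
#' Applies the angular-spectrum/Fresnel transfer function
#' \eqn{H(f) = \exp(-i \pi \lambda D |f|^2)} in frequency space and returns
#' the propagated intensity \eqn{|U_D|^2}. At distance 0 this is exactly
#' \eqn{|T|^2}. A warning is issued when the transfer function is aliased,
#' i.e. when its phase changes by more than pi between adjacent frequency
#' samples at the Nyquist frequency (condition
#' \eqn{\lambda D > N \cdot pixel^2} for the smaller image dimension).
#'
#' @param transmission Complex matrix (the object exit field).
#' @param distance_mm Propagation distance, mm.
#' @param wavelength_nm Wavelength, nm.
#' @param pixel_um Pixel size, um.
#' @return Real matrix of intensities.
#' @export
fresnel_propagate <- function(transmission, distance_mm, wavelength_nm, pixel_um) {
  if (distance_mm < 0) stopf("fresnel_propagate: distance must be >= 0")
  if (distance_mm == 0) return(Mod(transmission)^2)
  lambda_um <- wavelength_nm * 1e-3
  D_um <- distance_mm * 1e3
  n1 <- nrow(transmission); n2 <- ncol(transmission)
  # adequate sampling of H along an axis with n samples requires the phase
  # step between adjacent frequency samples at Nyquist to stay below pi,
  # i.e. lambda*D <= n*pixel^2; axes of extent 1 carry no frequency content
  n_eff <- if (any(c(n1, n2) > 1L)) min(c(n1, n2)[c(n1, n2) > 1L]) else 1L
  if (lambda_um * D_um > n_eff * pixel_um^2)
    warning(sprintf(paste0(
      "fresnel_propagate: transfer function aliased: lambda*D = %.3g um^2 ",
      "exceeds N*pixel^2 = %.3g um^2; decrease distance or pixel size"),
      lambda_um * D_um, n_eff * pixel_um^2))
  f1 <- fft_freq(n1, pixel_um)
  f2 <- fft_freq(n2, pixel_um)
  f2sq <- outer(f1^2, f2^2, `+`)
  H <- exp(-1i * pi * lambda_um * D_um * f2sq)
  U <- ifft2(fft2(transmission) * H)
  Mod(U)^2
}

#' Simulate a tomographic acquisition
#'
#' Composes [project_complex()] and [fresnel_propagate()] per projection and,
#' for a finite photon budget, replaces every detector pixel by
#' Poisson(N0 * I) / N0 using the beam's seeded generator. Intensities are
#' flat-field normalised (unit background).
#'
#' @param materials A `material_volume`.
#' @param beam A `beam_config`.
#' @param projections Optional precomputed `projection_set` (the distance-
#'   independent part), e.g. to acquire the same object at several distances.
#' @param verbose Log per-stage timings.
#' @return Object of class `sinogram`: list with `intensities` (array
#'   dim (n_z detector rows, n_t detector columns, n_angles) — note the
#'   angle-last storage order), `angles`, `beam`.
#' @export
acquire <- function(materials, beam, projections = NULL, verbose = FALSE) {
  stopifnot(inherits(beam, "beam_config"))
  if (is.null(projections))
    projections <- log_stage(verbose, "project", project_complex(materials, beam))
  stopifnot(inherits(projections, "projection_set"))
  dm <- dim(projections$phi)
  out <- array(0, dim = dm)
  log_stage(verbose, sprintf("propagate D=%gmm", beam$propagation_mm), {
    for (i in seq_len(dm[3])) {
      I <- fresnel_propagate(transmission_at(projections, i),
                             beam$propagation_mm, beam$wavelength_nm,
                             beam$detector_pixel_um)
      if (beam$psf_fwhm_px > 0)
        I <- gaussian_blur2d(I, beam$psf_fwhm_px / 2.354820045)
      out[, , i] <- I
    }
    NULL
  })
  if (is.finite(beam$photons_per_pixel)) {
    N0 <- beam$photons_per_pixel
    out <- with_seed(beam$rng_seed,
                     array(rpois(length(out), N0 * pmax(out, 0)) / N0, dim = dm))
  }
  structure(list(intensities = out, angles = projections$angles, beam = beam),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<sinogram> %d angles x %d rows x %d columns, D = %g mm\n",
              d[3], d[1], d[2], x$beam$propagation_mm))
  invisible(x)
}

#' Ring-artefact correction of a sinogram
#'
#' Detector gain defects are constant per detector pixel across projection
#' angles and reconstruct as rings. In the log domain, the per-pixel mean over
#' angles is compared with its running median along the detector column axis;
#' pixels whose residual exceeds an outlier gate (`max(5 * MAD, min_defect)`
#' per detector row) are renormalised toward the smoothed profile. Clean
#' sinograms pass through unchanged (no column passes the gate).
#'
#' @param sino A `sinogram`.
#' @param window Running-median window along detector columns (odd, default 5).
#' @param min_defect Minimum log-domain residual treated as a defect
#'   (default 0.005, i.e. a 0.5% gain error).
#' @return A corrected `sinogram`.
#' @export
ring_correct <- function(sino, window = 5L, min_defect = 0.005) {
  stopifnot(inherits(sino, "sinogram"))
  d <- dim(sino$intensities)
  if (d[3] < 8L) stopf("ring_correct: need >= 8 angles")
  eps <- 1e-12
  Lg <- log(pmax(sino$intensities, eps))
  m <- apply(Lg, c(1, 2), mean)                 # (rows z, columns t)
  sm <- t(apply(m, 1, running_median, window = window))
  r <- m - sm
  gate <- pmax(5 * apply(r, 1, function(x) mad(x, constant = 1.4826)), min_defect)
  defect <- abs(r) > gate
  if (any(defect)) {
    corr <- ifelse(defect, r, 0)
    sino$intensities <- exp(Lg - array(corr, dim = d))
  }
  sino
}

running_median <- function(x, window = 5L) {
  n <- length(x)
  h <- window %/% 2
  if (n <= window) return(rep(median(x), n))
  out <- x
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    out[i] <- median(x[lo:hi])
  }
  out
}

# Band-limited Ram-Lak filter kernel (spatial domain, unit sample spacing):
# h(0) = 1/4, h(n) = -1/(pi n)^2 for odd n, 0 for even n.
ramlak_kernel <- function(np) {
  n <- c(0:(np / 2), -(np / 2 - 1):-1)
  h <- numeric(np)
  h[n == 0] <- 0.25
  odd <- n %% 2 != 0
  h[odd] <- -1 / (pi * n[odd])^2
  h
}

#' Filtered backprojection reconstruction
#'
#' Slice-by-slice parallel-beam FBP of `-log(I)` (intensities clipped at
#' `log_floor` before the log). Projections are ramp-filtered (band-limited
#' Ram-Lak; optional Hann apodisation) via FFT with zero padding, then
#' backprojected with the pi/n_angles weighting. The result is the effective
#' linear attenuation coefficient in 1/um; for a pure-absorption contact-plane
#' acquisition this equals \eqn{4\pi\beta/\lambda}.
#'
#' @param sino A `sinogram` whose angles span 180 degrees.
#' @param window Ramp apodisation: "none" (pure ramp, default) or "hann".
#' @param log_floor Intensity clipping floor before the logarithm.
#' @return Object of class `recon_volume`: list with `values` (3D array,
#'   dim (n_z, n_y, n_x)), `voxel_size_um`, `provenance` (the beam config).
#' @export
reconstruct_fbp <- function(sino, window = c("none", "hann"), log_floor = 1e-9) {
  stopifnot(inherits(sino, "sinogram"))
  window <- match.arg(window)
  d <- dim(sino$intensities)
  nz <- d[1]; nt <- d[2]; na <- d[3]
  if (na < 2L) stopf("reconstruct_fbp: need >= 2 angles")
  p <- -log(pmax(sino$intensities, log_floor))

  np <- 2^ceiling(log2(2 * nt))
  H <- Re(fft(ramlak_kernel(np)))
  if (window == "hann") {
    f <- fft_freq(np, 1)
    H <- H * (0.5 + 0.5 * cos(pi * f / max(abs(f))))
  }
  # filter along t: reshape to (nt, nz*na), pad, FFT, multiply, inverse
  pm <- aperm(p, c(2, 1, 3))
  dim(pm) <- c(nt, nz * na)
  padded <- matrix(0, np, nz * na)
  padded[seq_len(nt), ] <- pm
  q <- Re(mvfft(mvfft(padded) * H, inverse = TRUE)) / np
  q <- q[seq_len(nt), , drop = FALSE]
  dim(q) <- c(nt, nz, na)
  q <- aperm(q, c(2, 1, 3))

  vol <- cpp_backproject(q, dim(q), sino$angles, nt, nt) * (pi / na)
  vol <- vol / sino$beam$detector_pixel_um   # per-voxel-step -> per um
  structure(list(values = vol, voxel_size_um = sino$beam$detector_pixel_um,
                 provenance = sino$beam),
            class = "recon_volume")
}

#' @export
print.recon_volume <- function(x, ...) {
  cat(sprintf("<recon_volume> %s voxels @ %.3g um, D = %g mm\n",
              paste(dim(x$values), collapse = "x"), x$voxel_size_um,
              x$provenance$propagation_mm))
  invisible(x)
}
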