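#' Spherical-lesion tissue phantom
#'
#' A homogeneous semi-infinite background containing one spherical
#' absorber. Construction warns (rather than errors) when a parameter
#' leaves the ranges used by the synthetic pretraining cohort, so that
#' deliberately out-of-range phantoms remain possible.
#'
#' @param background,lesion [optical_properties()] for the two
#'   compartments, one value per wavelength.
#' @param lesion_center Length-3 numeric, cm; z is the depth below the
#'   probe plane.
#' @param lesion_radius Sphere radius, cm.
#' @return An object of class `tissue_phantom`.
#' @export
tissue_phantom <- function(background, lesion, lesion_center, lesion_radius) {
  stopifnot(inherits(background, "optical_props"),
            inherits(lesion, "optical_props"),
            length(lesion_center) == 3L, length(lesion_radius) == 1L)
  if (length(background$mua) != length(lesion$mua))
    stop("background and lesion must cover the same wavelengths")
  rng_warn <- function(x, lo, hi, what)
    if (any(x < lo | x > hi))
      warning(sprintf("%s outside the simulated cohort range [%g, %g]",
                      what, lo, hi), call. = FALSE)
  rng_warn(lesion_radius, 0.375, 1.5, "lesion radius (cm)")
  rng_warn(lesion_center[3], 0.7, 2.7, "lesion depth (cm)")
  rng_warn(lesion$mua, 0.06, 0.30, "lesion mua (1/cm)")
  rng_warn(lesion$musp, 4, 8, "lesion musp (1/cm)")
  rng_warn(background$mua, 0.01, 0.06, "background mua (1/cm)")
  rng_warn(background$musp, 4, 8, "background musp (1/cm)")
  structure(list(background = background, lesion = lesion,
                 lesion_center = as.numeric(lesion_center),
                 lesion_radius = lesion_radius),
            class = "tissue_phantom")
}

# cubic voxelisation of a sphere; grid symmetric about the centre so that
# forward and inverse discretisations can be made to coincide
sphere_voxels <- function(center, radius, edge) {
  n <- max(1L, ceiling(2 * radius / edge - 1e-9))
  off <- (seq_len(n) - (n + 1) / 2) * edge
  g <- expand.grid(x = center[1] + off, y = center[2] + off,
                   z = center[3] + off)
  g <- as.matrix(g)
  keep <- rowSums(sweep(g, 2, center)^2) <= radius^2
  list(centers = g[keep, , drop = FALSE], volume = edge^3)
}

#' Simulate frequency-domain DOT measurements for lesion and reference side
#'
#' Analytic forward model: the reference (contralateral) side is the
#' homogeneous semi-infinite field; the lesion side perturbs it with the
#' first-order scattered field of the spherical absorber, summed over
#' cubic voxels. Two compositions are available: `"rytov"` (default)
#' exponentiates the normalised scattered field,
#' `u_l = u_0 exp(u_sc / u_0)`, which keeps the measurement physical
#' (the lesion-side amplitude can only be attenuated, never
#' sign-flipped, so the perturbation saturates for strong absorbers);
#' `"born"` adds it linearly,
#' `u_l = u_0 + u_sc`, making the perturbation exactly proportional to
#' the absorption contrast — the regime the Born inversion assumes and
#' the right mode for inverse-consistency studies. The two agree to
#' first order in the contrast. Each repeated measurement applies an
#' independent rigid in-plane probe offset (probe jitter) and
#' independent multiplicative amplitude and additive phase noise to both
#' sides.
#'
#' @param phantom A [tissue_phantom()].
#' @param geometry A [probe_geometry()].
#' @param wavelengths Wavelengths in nm (must match the phantom's
#'   per-wavelength optical properties).
#' @param n_repeats Number of repeated lesion measurements.
#' @param probe_jitter_sd In-plane rigid probe offset SD, cm.
#' @param amp_noise_sd Relative amplitude noise SD.
#' @param phase_noise_sd_deg Phase noise SD, degrees.
#' @param voxel_edge Born volume-sum voxel edge, cm.
#' @param scattering_model "rytov" (saturating, default) or "born"
#'   (exactly linear in the absorption contrast).
#' @param seed Integer seed; the output is a pure function of it.
#' @return An object of class `measurement_set` with complex arrays
#'   `u_lesion` and `u_reference` of dim (source, detector, wavelength,
#'   repeat).
#' @export
simulate_measurements <- function(phantom, geometry,
                                  wavelengths = default_wavelengths(),
                                  n_repeats = 3,
                                  probe_jitter_sd = 0.25,
                                  amp_noise_sd = 0.01,
                                  phase_noise_sd_deg = 0.5,
                                  voxel_edge = 0.1,
                                  scattering_model = c("rytov", "born"),
                                  seed = NULL) {
  stopifnot(inherits(phantom, "tissue_phantom"),
            inherits(geometry, "probe_geometry"), n_repeats >= 1)
  scattering_model <- match.arg(scattering_model)
  if (length(wavelengths) != length(phantom$background$mua))
    stop("wavelength count does not match phantom optical properties")
  if (phantom$lesion_center[3] < phantom$lesion_radius)
    stop("lesion sphere intersects the probe plane (depth < radius)")
  if (!is.null(seed)) set.seed(seed)
  S <- nrow(geometry$sources); D <- nrow(geometry$detectors)
  W <- length(wavelengths); omega <- 2 * pi * geometry$modulation_frequency
  ul <- ur <- array(complex(real = 0), c(S, D, W, n_repeats))
  # homogeneous field per wavelength (lateral translation invariant, so
  # probe jitter does not affect it)
  u0 <- vector("list", W)
  for (w in seq_len(W))
    u0[[w]] <- cpp_green_matrix(geometry$sources, geometry$detectors,
                                phantom$background$mua[w],
                                phantom$background$musp[w],
                                omega, C_TISSUE, R_EFF)
  deg <- pi / 180
  for (r in seq_len(n_repeats)) {
    off <- if (probe_jitter_sd > 0) rnorm(2, sd = probe_jitter_sd) else c(0, 0)
    # moving the probe by +off equals moving the lesion by -off
    ctr <- phantom$lesion_center - c(off, 0)
    vox <- sphere_voxels(ctr, phantom$lesion_radius, voxel_edge)
    nv <- nrow(vox$centers)
    for (w in seq_len(W)) {
      dmua <- phantom$lesion$mua[w] - phantom$background$mua[w]
      usc <- if (abs(dmua) > 0 && nv > 0) {
        cpp_born_scatter(geometry$sources, geometry$detectors, vox$centers,
                         rep(vox$volume, nv), rep(dmua, nv),
                         phantom$background$mua[w], phantom$background$musp[w],
                         omega, C_TISSUE, R_EFF)
      } else matrix(complex(real = 0), S, D)
      base_l <- if (scattering_model == "rytov")
        u0[[w]] * exp(usc / u0[[w]]) else u0[[w]] + usc
      base_r <- u0[[w]]
      if (amp_noise_sd > 0 || phase_noise_sd_deg > 0) {
        nz <- function(u) {
          a <- matrix(rnorm(S * D, sd = amp_noise_sd), S, D)
          p <- matrix(rnorm(S * D, sd = phase_noise_sd_deg * deg), S, D)
          u * (1 + a) * exp(1i * p)
        }
        base_l <- nz(base_l); base_r <- nz(base_r)
      }
      ul[, , w, r] <- base_l
      ur[, , w, r] <- base_r
    }
  }
  structure(list(u_lesion = ul, u_reference = ur, geometry = geometry,
                 wavelengths = wavelengths, seed = seed,
                 noise = list(probe_jitter_sd = probe_jitter_sd,
                              amp_noise_sd = amp_noise_sd,
                              phase_noise_sd_deg = phase_noise_sd_deg)),
            class = "measurement_set")
}

#' Sample a random lesion phantom of a given diagnostic class
#'
#' Draws phantom parameters from the simulated-cohort ranges (lesion
#' radius 0.375--1.5 cm, centre depth 0.7--2.7 cm, background mua
#' 0.01--0.06 1/cm, all musp 4--8 1/cm). The lesion absorption is drawn
#' from a class-specific sub-range: benign lesions have low absorption,
#' malignant high. The default "gap" contrast leaves the sub-ranges
#' disjoint (benign 0.06--0.14, malignant 0.16--0.30 1/cm); "overlap"
#' makes them overlap (benign 0.06--0.18, malignant 0.12--0.30) for a
#' harder cohort. The lesion radius is drawn from class-conditional
#' beta distributions on the Table range whose means (0.74 cm benign,
#' 1.03 cm malignant) mirror the clinical size statistics of the
#' patient population (mean maximum dimension 1.48 cm benign versus
#' 2.05 cm malignant); depth, background and scattering are class-
#' independent. Absorption spectra are flat across wavelengths.
#'
#' @param class_label "benign" or "malignant".
#' @param seed Integer seed; sampling is deterministic under it.
#' @param contrast "gap" (default) or "overlap".
#' @param n_wavelengths Number of wavelengths to populate.
#' @return A [tissue_phantom()].
#' @export
sample_phantom <- function(class_label = c("benign", "malignant"),
                           seed = NULL, contrast = c("gap", "overlap"),
                           n_wavelengths = 4) {
  class_label <- match.arg(class_label)
  contrast <- match.arg(contrast)
  if (!is.null(seed)) set.seed(seed)
  radius <- 0.375 + 1.125 * (if (class_label == "benign")
    stats::rbeta(1, 1.6, 3.34) else stats::rbeta(1, 2.33, 1.67))
  depth <- runif(1, max(0.7, radius + 0.2), 2.7)
  lateral <- runif(2, -0.5, 0.5)
  bg_mua <- runif(1, 0.01, 0.06)
  bg_musp <- runif(1, 4, 8)
  les_musp <- runif(1, 4, 8)
  rng <- if (contrast == "gap") {
    if (class_label == "benign") c(0.06, 0.14) else c(0.16, 0.30)
  } else {
    if (class_label == "benign") c(0.06, 0.18) else c(0.12, 0.30)
  }
  les_mua <- runif(1, rng[1], rng[2])
  w1 <- rep(1, n_wavelengths)
  tissue_phantom(optical_properties(bg_mua * w1, bg_musp * w1),
                 optical_properties(les_mua * w1, les_musp * w1),
                 c(lateral, depth), radius)
}
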