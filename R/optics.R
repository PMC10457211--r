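#' Optical properties of a tissue compartment
#'
#' Bundles absorption and reduced scattering coefficients, one value per
#' wavelength. Both are in 1/cm. Validity of the diffusion approximation
#' requires `mua < musp`.
#'
#' @param mua Absorption coefficient(s), 1/cm, one per wavelength.
#' @param musp Reduced scattering coefficient(s), 1/cm, recycled to the
#'   length of `mua` if scalar.
#' @return An object of class `optical_props`.
#' @export
optical_properties <- function(mua, musp) {
  if (length(musp) == 1L) musp <- rep(musp, length(mua))
  if (length(mua) != length(musp))
    stop("mua and musp must have the same length")
  if (any(!is.finite(mua)) || any(!is.finite(musp)))
    stop("optical properties must be finite")
  if (any(mua <= 0) || any(musp <= 0))
    stop("optical properties must be positive")
  if (any(mua >= musp))
    stop("diffusion regime requires mua < musp")
  structure(list(mua = mua, musp = musp), class = "optical_props")
}

#' Default near-infrared wavelengths (nm)
#'
#' Four wavelengths representative of frequency-domain DOT breast imaging
#' systems.
#'
#' @return Numeric vector of four wavelengths in nm.
#' @export
default_wavelengths <- function() c(740, 780, 808, 830)

#' Probe geometry for a reflection-mode DOT hand probe
#'
#' Source and detector fibre positions on the probe face (the z = 0 plane,
#' all coordinates in cm) plus the source modulation frequency.
#'
#' @param source_positions Numeric matrix, one row per source, columns
#'   x, y, z (cm). All z must be 0.
#' @param detector_positions Same layout for detectors.
#' @param modulation_frequency Source intensity modulation frequency, Hz.
#' @return An object of class `probe_geometry`.
#' @export
probe_geometry <- function(source_positions, detector_positions,
                           modulation_frequency = 140e6) {
  s <- as.matrix(source_positions); d <- as.matrix(detector_positions)
  if (ncol(s) != 3L || ncol(d) != 3L) stop("positions must be n x 3 matrices")
  if (nrow(s) < 1L || nrow(d) < 1L) stop("need at least 1 source and 1 detector")
  if (any(abs(s[, 3]) > 1e-9) || any(abs(d[, 3]) > 1e-9))
    stop("all probe positions must lie on the z = 0 plane")
  sep <- sqrt(outer(s[, 1], d[, 1], "-")^2 + outer(s[, 2], d[, 2], "-")^2)
  if (any(sep <= 0.1))
    stop("source-detector separation must exceed 0.1 cm")
  structure(list(sources = s, detectors = d,
                 modulation_frequency = modulation_frequency),
            class = "probe_geometry")
}

#' Default circular probe layout
#'
#' Nine sources on an inner ring and fourteen detectors on two outer rings
#' of a circular probe face, a layout representative of hand-held
#' reflection-mode US-guided DOT probes.
#'
#' @param n_sources,n_detectors Number of sources / detectors.
#' @param diameter Probe face diameter, cm.
#' @param modulation_frequency Modulation frequency, Hz.
#' @return A [probe_geometry()] object.
#' @export
default_probe_geometry <- function(n_sources = 9, n_detectors = 14,
                                   diameter = 9, modulation_frequency = 140e6) {
  ring <- function(n, r, phase = 0) {
    a <- phase + 2 * pi * (seq_len(n) - 1) / n
    cbind(r * cos(a), r * sin(a), 0)
  }
  src <- ring(n_sources, 0.18 * diameter)
  n1 <- ceiling(n_detectors / 2); n2 <- n_detectors - n1
  det <- rbind(ring(n1, 0.32 * diameter, pi / n1),
               ring(n2, 0.45 * diameter))
  probe_geometry(src, det, modulation_frequency)
}

#' Frequency-domain diffusion Green's function for a semi-infinite medium
#'
#' Photon-density Green's function of the frequency-domain diffusion
#' equation in the half space z >= 0 with an extrapolated zero boundary
#' (image-source method). The complex wavenumber is
#' k^2 = (-mua + i omega / c) / D with D = 1/(3 (mua + musp)), and the
#' image plane sits at z = -z_b with z_b = 2 D (1 + R_eff)/(1 - R_eff).
#'
#' @param p_a,p_b Points in the half space, numeric length-3 vectors or
#'   n x 3 matrices (cm).
#' @param props [optical_properties()] (the first wavelength is used
#'   unless `wavelength_index` says otherwise).
#' @param modulation_frequency Modulation frequency in Hz (0 gives the
#'   DC / continuous-wave kernel).
#' @param wavelength_index Which wavelength of `props` to use.
#' @return Complex matrix of field values, `nrow(p_a)` x `nrow(p_b)`.
#' @export
green_semi_infinite <- function(p_a, p_b, props, modulation_frequency = 140e6,
                                wavelength_index = 1) {
  a <- if (is.null(dim(p_a))) matrix(p_a, 1) else as.matrix(p_a)
  b <- if (is.null(dim(p_b))) matrix(p_b, 1) else as.matrix(p_b)
  if (any(a[, 3] < 0) || any(b[, 3] < 0))
    stop("points must lie in the half space z >= 0")
  mua <- props$mua[wavelength_index]; musp <- props$musp[wavelength_index]
  g <- cpp_green_matrix(a, b, mua, musp, 2 * pi * modulation_frequency,
                        C_TISSUE, R_EFF)
  if (length(g) == 1L) g[1, 1] else g
}
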