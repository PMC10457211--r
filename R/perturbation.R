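#' Normalised complex perturbation between lesion and reference side
#'
#' Element-wise `(u_lesion / u_reference) - 1`, flattened over
#' (source, detector, wavelength, repeat) with source varying fastest.
#' For a low-absorption (benign-like) lesion both sides are similar and
#' the perturbation clusters near the origin; a strong absorber pulls the
#' real part toward -1.
#'
#' @param ms A `measurement_set`.
#' @return An object of class `perturbation` with fields `values`
#'   (complex vector) and the four index counts.
#' @export
compute_perturbation <- function(ms) {
  stopifnot(inherits(ms, "measurement_set"))
  zero <- which(ms$u_reference == 0)
  if (length(zero)) {
    idx <- arrayInd(zero[1], dim(ms$u_reference))
    stop(sprintf(paste0("zero reference measurement at (source %d, ",
                        "detector %d, wavelength %d, repeat %d)"),
                 idx[1], idx[2], idx[3], idx[4]))
  }
  d <- dim(ms$u_lesion)
  v <- as.vector(ms$u_lesion / ms$u_reference - 1)
  # identical measurements must give an exactly zero perturbation;
  # complex division alone leaves rounding residue
  v[as.vector(ms$u_lesion == ms$u_reference)] <- 0 + 0i
  structure(list(values = v,
                 n_sources = d[1], n_detectors = d[2],
                 n_wavelengths = d[3], n_repeats = d[4]),
            class = "perturbation")
}

#' Bivariate histogram of complex perturbations
#'
#' Bins perturbation points on a 32 x 32 grid, x-axis the real part and
#' y-axis the imaginary part (grid rows index the imaginary axis, columns
#' the real axis). Out-of-range points are clipped to the nearest edge
#' bin so that the raw count always equals the number of input points.
#' Bins are half-open `[lo, hi)` except the last, which is closed. The
#' binned grid is then divided by
#' `n_files * n_wavelengths * n_detectors`, which makes histograms
#' comparable across systems with different channel counts.
#'
#' @param perts A `perturbation` or a list of them (several measurement
#'   files of one patient).
#' @param real_range,imag_range Axis ranges.
#' @param n_files Averaging file count; defaults to the number of
#'   perturbation objects supplied.
#' @param bins Number of bins per axis.
#' @param magnitude_filter Optional modulus cutoff; points with
#'   `Mod(pert)` above it are dropped before binning (off by default).
#' @return An object of class `perturbation_histogram` with the averaged
#'   `grid`, bin edges, `divisor` and raw point count `n_points`.
#' @export
build_histogram <- function(perts, real_range = c(-1, 1),
                            imag_range = c(-1, 1), n_files = NULL,
                            bins = 32, magnitude_filter = Inf) {
  if (inherits(perts, "perturbation")) perts <- list(perts)
  if (!length(perts)) stop("no perturbations supplied")
  stopifnot(all(vapply(perts, inherits, TRUE, "perturbation")),
            diff(real_range) > 0, diff(imag_range) > 0)
  if (is.null(n_files)) n_files <- length(perts)
  nw <- perts[[1]]$n_wavelengths; nd <- perts[[1]]$n_detectors
  v <- unlist(lapply(perts, `[[`, "values"))
  v <- v[is.finite(Re(v)) & is.finite(Im(v))]
  if (is.finite(magnitude_filter)) v <- v[Mod(v) <= magnitude_filter]
  if (!length(v)) stop("no perturbation points to bin")
  re <- pmin(pmax(Re(v), real_range[1]), real_range[2])
  im <- pmin(pmax(Im(v), imag_range[1]), imag_range[2])
  re_edges <- seq(real_range[1], real_range[2], length.out = bins + 1)
  im_edges <- seq(imag_range[1], imag_range[2], length.out = bins + 1)
  jr <- pmin(findInterval(re, re_edges), bins)
  ji <- pmin(findInterval(im, im_edges), bins)
  divisor <- as.numeric(n_files) * nw * nd
  grid <- matrix(tabulate((jr - 1) * bins + ji, nbins = bins * bins),
                 bins, bins) / divisor
  structure(list(grid = grid, real_edges = re_edges, imag_edges = im_edges,
                 divisor = divisor, n_points = length(v)),
            class = "perturbation_histogram")
}

#' Stack histograms into a CNN input array
#'
#' @param hists List of `perturbation_histogram` objects (or bare 32 x 32
#'   matrices).
#' @return Numeric array of dim (32, 32, 1, n).
#' @export
histogram_input <- function(hists) {
  if (inherits(hists, "perturbation_histogram")) hists <- list(hists)
  g <- lapply(hists, function(h) if (is.matrix(h)) h else h$grid)
  b <- nrow(g[[1]])
  array(unlist(g), c(b, b, 1, length(g)))
}
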