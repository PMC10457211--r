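#' Born sensitivity matrix on a dual mesh
#'
#' Row m = (source s, detector d; source index varying fastest) and
#' column j carry the normalised first-Born weight
#' `-G(s, j) G(j, d) V_j / (D U0(s, d))`, built from the reference-side
#' (background) optical properties, so that `W %*% delta_mua` predicts
#' the dimensionless perturbation of [compute_perturbation()].
#'
#' @param geometry A [probe_geometry()].
#' @param background [optical_properties()] of the reference side.
#' @param mesh A [build_dual_mesh()] mesh.
#' @param wavelength_index Which wavelength of `background` to use.
#' @return Object of class `sensitivity_matrix` with complex matrix `w`
#'   (n_measurements x n_voxels), the background properties and the
#'   homogeneous field `u0`.
#' @export
assemble_sensitivity <- function(geometry, background, mesh,
                                 wavelength_index = 1) {
  stopifnot(inherits(geometry, "probe_geometry"),
            inherits(background, "optical_props"),
            inherits(mesh, "dual_mesh"))
  mua <- background$mua[wavelength_index]
  musp <- background$musp[wavelength_index]
  omega <- 2 * pi * geometry$modulation_frequency
  w0 <- cpp_sensitivity(geometry$sources, geometry$detectors, mesh$centers,
                        mesh$volumes, mua, musp, omega, C_TISSUE, R_EFF)
  u0 <- cpp_green_matrix(geometry$sources, geometry$detectors, mua, musp,
                         omega, C_TISSUE, R_EFF)
  structure(list(w = w0 / as.vector(u0), u0 = as.vector(u0),
                 background = background,
                 wavelength_index = wavelength_index),
            class = "sensitivity_matrix")
}

#' Reconstruction solver configuration
#'
#' @param lambda Tikhonov regularisation parameter; `NULL` selects
#'   0.1 times the largest singular value of the stacked real system
#'   (estimated by 20 power iterations).
#' @param max_iterations Conjugate-gradient iteration cap.
#' @param tol Relative residual tolerance on the normal equations.
#' @param track_objective Record the per-iteration objective value
#'   (costs one extra matrix-vector product per iteration).
#' @param precision "double" (reference) or "single" (the faster
#'   engine used for bulk cohort reconstructions).
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(lambda = NULL, max_iterations = 200, tol = 1e-8,
                         track_objective = TRUE,
                         precision = c("double", "single")) {
  stopifnot(is.null(lambda) || lambda >= 0, max_iterations >= 1)
  structure(list(lambda = lambda, max_iterations = max_iterations,
                 tol = tol, track_objective = track_objective,
                 precision = match.arg(precision)),
            class = "recon_config")
}

#' Tikhonov-regularised conjugate-gradient Born inversion
#'
#' Minimises `||pert - W x||^2 + lambda^2 ||x||^2` by conjugate gradient
#' on the normal equations. A complex system is stacked as real and
#' imaginary rows; the solution is constrained real (the absorption
#' change is physical). The objective is non-increasing across
#' iterations.
#'
#' @param w A `sensitivity_matrix` or a numeric/complex matrix.
#' @param pert Data vector (complex allowed), length `nrow(w)`.
#' @param config A [recon_config()].
#' @return List with `delta_mua` (real solution), `lambda`, `iterations`,
#'   `objective` (per-iteration trace) and `converged`.
#' @export
solve_cg <- function(w, pert, config = recon_config()) {
  if (inherits(w, "sensitivity_matrix")) w <- w$w
  if (is.complex(w) || is.complex(pert)) {
    a <- rbind(Re(w), Im(w))
    b <- c(Re(pert), Im(pert))
  } else {
    a <- w; b <- as.numeric(pert)
  }
  if (length(b) != nrow(a)) stop("perturbation length does not match W rows")
  lambda <- if (is.null(config$lambda)) -1 else config$lambda
  sol <- cpp_cg(a, b, lambda, 20L, as.integer(config$max_iterations),
                config$tol, isTRUE(config$track_objective),
                identical(config$precision, "single"))
  if (sol$lambda == 0 && !sol$converged)
    warning("lambda = 0 and CG not converged: returning the current ",
            "minimum-norm iterate")
  list(delta_mua = as.numeric(sol$x), lambda = sol$lambda,
       iterations = sol$iterations, objective = as.numeric(sol$objective),
       converged = sol$converged)
}

#' Molar extinction table for oxy- and deoxy-haemoglobin
#'
#' Compiled-in effective extinction coefficients (per-microMolar,
#' natural-log basis: `mua = eps %*% c(HbO2, Hb)` with concentrations in
#' microMolar and mua in 1/cm) at the default near-infrared wavelengths,
#' from the standard tabulated base-10 molar extinction values.
#'
#' @param wavelengths Wavelengths in nm; must be among the tabulated
#'   740, 780, 808, 830 unless `table` is supplied.
#' @param table Optional user override: data.frame with columns
#'   `wavelength`, `hbo2`, `hb` in base-10 cm^-1 M^-1.
#' @return Matrix (n wavelengths x 2), columns HbO2 and Hb, units
#'   cm^-1 uM^-1.
#' @export
hb_extinction <- function(wavelengths = default_wavelengths(), table = NULL) {
  if (is.null(table))
    table <- data.frame(wavelength = c(740, 780, 808, 830),
                        hbo2 = c(446, 710, 844, 974),
                        hb = c(1403.5, 1096.0, 723.5, 693.0))
  i <- match(wavelengths, table$wavelength)
  if (anyNA(i))
    stop("no tabulated extinction values for wavelength(s) ",
         paste(wavelengths[is.na(i)], collapse = ", "),
         " nm; supply `table`")
  e <- as.matrix(table[i, c("hbo2", "hb")]) * log(10) / 1e6
  dimnames(e) <- list(paste0(wavelengths, "nm"), c("HbO2", "Hb"))
  if (qr(e)$rank < 2) stop("extinction matrix is rank deficient")
  e
}

#' Unmix multi-wavelength absorption into haemoglobin concentrations
#'
#' Per-voxel least-squares solve of `eps %*% c(HbO2, Hb) = mua_total`
#' where `mua_total = background mua + delta mua` over the measurement
#' wavelengths. Total haemoglobin is `HbO2 + Hb`, clamped at zero.
#'
#' @param delta_mua Matrix (n voxels x n wavelengths) of reconstructed
#'   absorption changes, 1/cm.
#' @param background_mua Reference-side absorption per wavelength, 1/cm.
#' @param ext Extinction matrix from [hb_extinction()].
#' @return List with vectors `hbo2`, `hb`, `thb` (microMolar).
#' @export
unmix_thb <- function(delta_mua, background_mua, ext = hb_extinction()) {
  delta_mua <- as.matrix(delta_mua)
  if (ncol(delta_mua) != nrow(ext))
    stop("delta_mua must have one column per extinction wavelength")
  if (length(background_mua) != nrow(ext))
    stop("background_mua must have one value per wavelength")
  if (qr(ext)$rank < 2) stop("extinction matrix is rank deficient")
  mua_tot <- sweep(delta_mua, 2, background_mua, "+")
  pinv <- solve(crossprod(ext), t(ext))      # 2 x n_wavelengths
  conc <- mua_tot %*% t(pinv)
  list(hbo2 = conc[, 1], hb = conc[, 2],
       thb = pmax(conc[, 1] + conc[, 2], 0))
}

#' Resample voxel-wise total haemoglobin onto depth-slice images
#'
#' Nearest-voxel resampling onto three 32 x 32 lateral grids at the given
#' depths, the input format of the DOT-image CNN branch. Negative values
#' are clamped to zero.
#'
#' @param voxel_thb Per-voxel tHb (microMolar), length = mesh voxel count.
#' @param mesh The `dual_mesh` the values live on.
#' @param slice_depths Three slice depths, cm; default is the ROI centre
#'   depth and +/- 0.5 cm.
#' @param n_pixels Lateral grid size.
#' @return Object of class `thb_map`: array dim (n_pixels, n_pixels, 3)
#'   with attributes `slice_depths` and `pixel_pitch`.
#' @export
render_thb_image <- function(voxel_thb, mesh, slice_depths = NULL,
                             n_pixels = 32) {
  stopifnot(inherits(mesh, "dual_mesh"),
            length(voxel_thb) == nrow(mesh$centers))
  if (is.null(slice_depths))
    slice_depths <- mesh$roi$center[3] + c(-0.5, 0, 0.5)
  slice_depths <- pmin(pmax(slice_depths, 1e-6), mesh$domain[3])
  if (length(slice_depths) != 3L) stop("need exactly 3 slice depths")
  px <- mesh$domain[1] / n_pixels
  xs <- -mesh$domain[1] / 2 + (seq_len(n_pixels) - 0.5) * px
  ys <- -mesh$domain[2] / 2 + (seq_len(n_pixels) - 0.5) *
    (mesh$domain[2] / n_pixels)
  out <- array(0, c(n_pixels, n_pixels, 3))
  for (k in 1:3) {
    pts <- as.matrix(expand.grid(x = xs, y = ys))
    pts <- cbind(pts, slice_depths[k])
    idx <- cpp_nearest_voxel(pts, mesh$centers)
    out[, , k] <- matrix(pmax(voxel_thb[idx], 0), n_pixels, n_pixels)
  }
  structure(out, slice_depths = slice_depths, pixel_pitch = px,
            class = "thb_map")
}

#' US-guided Born reconstruction to a total-haemoglobin map
#'
#' Full inversion chain for one lesion: perturbations averaged over
#' repeats per wavelength, dual mesh from the ultrasound ROI, per-
#' wavelength Tikhonov-CG solves, haemoglobin unmixing and slice
#' rendering. The unknowns are volume-weighted (`delta_mua * V`), the
#' dual-mesh convention that concentrates the reconstruction in the fine
#' region and improves quantification.
#'
#' @param ms A `measurement_set`.
#' @param roi_center,roi_radius Ultrasound guidance (cm).
#' @param background Reference-side [optical_properties()].
#' @param config A [recon_config()].
#' @param mesh Optional pre-built mesh (defaults to
#'   [build_dual_mesh()] on the ROI).
#' @param ext Extinction matrix.
#' @param slice_depths Passed to [render_thb_image()].
#' @param linearization Data linearization: "rytov" (default) inverts
#'   `log(u_lesion / u_reference)`, the consistent choice for saturating
#'   measurements; "born" inverts the raw perturbation, the consistent
#'   choice for strictly linear (Born) data.
#' @return Object of class `dot_reconstruction`: the `thb_map`, the
#'   per-voxel `delta_mua` matrix, voxel `thb`, the mesh, and solver
#'   diagnostics.
#' @export
reconstruct_thb <- function(ms, roi_center, roi_radius, background,
                            config = recon_config(), mesh = NULL,
                            ext = hb_extinction(ms$wavelengths),
                            slice_depths = NULL,
                            linearization = c("rytov", "born")) {
  stopifnot(inherits(ms, "measurement_set"))
  linearization <- match.arg(linearization)
  pert <- compute_perturbation(ms)
  d <- dim(ms$u_lesion)
  parr <- array(pert$values, d)
  if (linearization == "rytov") parr <- log(1 + parr)
  if (is.null(mesh)) mesh <- build_dual_mesh(roi_center, roi_radius)
  nvox <- nrow(mesh$centers)
  nw <- d[3]
  dmua <- matrix(0, nvox, nw)
  diag_list <- vector("list", nw)
  cfg <- config
  wv <- NULL
  flat <- length(unique(background$mua)) == 1L &&
    length(unique(background$musp)) == 1L
  for (w in seq_len(nw)) {
    pw <- apply(parr[, , w, , drop = FALSE], c(1, 2), mean)
    if (is.null(wv) || !flat) {
      sens <- assemble_sensitivity(ms$geometry, background, mesh, w)
      # volume-weighted unknowns u = delta_mua * V
      wv <- sweep(sens$w, 2, mesh$volumes, "/")
    }
    sol <- solve_cg(wv, as.vector(pw), cfg)
    # lambda is selected once per case (estimated at the first
    # wavelength) and shared across the per-wavelength solves
    if (w == 1L && is.null(cfg$lambda)) cfg$lambda <- sol$lambda
    dmua[, w] <- sol$delta_mua / mesh$volumes
    diag_list[[w]] <- sol[c("lambda", "iterations", "objective",
                            "converged")]
  }
  un <- unmix_thb(dmua, background$mua, ext)
  img <- render_thb_image(un$thb, mesh, slice_depths)
  structure(list(thb_map = img, delta_mua = dmua, voxel_thb = un$thb,
                 hbo2 = un$hbo2, hb = un$hb, mesh = mesh,
                 solver = diag_list),
            class = "dot_reconstruction")
}

#' Extract the 32 x 32 x 3 image array from a reconstruction
#' @param rec A `dot_reconstruction` or `thb_map`.
#' @return Numeric array dim (32, 32, 3).
#' @export
thb_image <- function(rec) {
  m <- if (inherits(rec, "dot_reconstruction")) rec$thb_map else rec
  array(as.numeric(m), dim(m))
}
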