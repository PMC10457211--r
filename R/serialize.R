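# plain-text serialization: CSV tables with full double precision plus a
# JSON sidecar for metadata, so cohorts round-trip exactly across
# platforms without binary formats

fmt <- function(x) sprintf("%.17g", x)

#' Write / read a measurement set as plain text
#'
#' One CSV row per (source, detector, wavelength, repeat) with real and
#' imaginary parts at full double precision, and a JSON sidecar holding
#' the probe geometry, wavelengths and noise metadata.
#'
#' @param ms A `measurement_set`.
#' @param path Base path; `<path>.csv` and `<path>.json` are written.
#' @return `write_measurement_set` returns `path` invisibly;
#'   `read_measurement_set` the reconstructed `measurement_set`.
#' @export
write_measurement_set <- function(ms, path) {
  d <- dim(ms$u_lesion)
  idx <- expand.grid(source = seq_len(d[1]), detector = seq_len(d[2]),
                     wavelength = seq_len(d[3]), rep = seq_len(d[4]))
  df <- data.frame(idx,
                   re_lesion = fmt(Re(ms$u_lesion)),
                   im_lesion = fmt(Im(ms$u_lesion)),
                   re_ref = fmt(Re(ms$u_reference)),
                   im_ref = fmt(Im(ms$u_reference)))
  write.csv(df, paste0(path, ".csv"), row.names = FALSE, quote = FALSE)
  meta <- list(dim = d, wavelengths = ms$wavelengths,
               modulation_frequency = ms$geometry$modulation_frequency,
               sources = ms$geometry$sources,
               detectors = ms$geometry$detectors,
               noise = ms$noise, seed = ms$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_measurement_set
#' @export
read_measurement_set <- function(path) {
  df <- read.csv(paste0(path, ".csv"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(meta$dim)
  ul <- array(complex(real = as.numeric(df$re_lesion),
                      imaginary = as.numeric(df$im_lesion)), d)
  ur <- array(complex(real = as.numeric(df$re_ref),
                      imaginary = as.numeric(df$im_ref)), d)
  geo <- probe_geometry(meta$sources, meta$detectors,
                        meta$modulation_frequency)
  structure(list(u_lesion = ul, u_reference = ur, geometry = geo,
                 wavelengths = as.numeric(meta$wavelengths),
                 seed = meta$seed,
                 noise = as.list(meta$noise)),
            class = "measurement_set")
}

#' Write / read a perturbation histogram as plain text
#'
#' @param h A `perturbation_histogram`.
#' @param path Base path; `<path>.csv` (the 32 x 32 grid) and
#'   `<path>.json` (edges, divisor, counts) are written.
#' @return The path / the histogram.
#' @export
write_histogram <- function(h, path) {
  m <- matrix(fmt(h$grid), nrow(h$grid))
  utils::write.table(m, paste0(path, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(real_edges = h$real_edges,
                            imag_edges = h$imag_edges,
                            divisor = h$divisor, n_points = h$n_points),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname write_histogram
#' @export
read_histogram <- function(path) {
  g <- as.matrix(utils::read.table(paste0(path, ".csv"), sep = ","))
  dimnames(g) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(grid = g, real_edges = as.numeric(meta$real_edges),
                 imag_edges = as.numeric(meta$imag_edges),
                 divisor = as.numeric(meta$divisor),
                 n_points = as.integer(meta$n_points)),
            class = "perturbation_histogram")
}

#' Cohort manifest table
#'
#' @param cohort A cohort list.
#' @param file Optional CSV path to write.
#' @return Data frame of case ids, labels and phantom parameters.
#' @export
cohort_manifest <- function(cohort, file = NULL) {
  df <- do.call(rbind, lapply(cohort, function(cs) {
    ph <- cs$phantom
    data.frame(case_id = cs$case_id, label = cs$label,
               lesion_radius = ph$lesion_radius,
               lesion_depth = ph$lesion_center[3],
               lesion_mua = ph$lesion$mua[1],
               lesion_musp = ph$lesion$musp[1],
               background_mua = ph$background$mua[1],
               background_musp = ph$background$musp[1])
  }))
  if (!is.null(file)) write.csv(df, file, row.names = FALSE)
  df
}
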