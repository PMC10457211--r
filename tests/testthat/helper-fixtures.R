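# shared fixtures, built once per session and cached

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, .fx)) assign(name, expr, .fx)
  get(name, .fx)
}

fx_geometry <- function() fixture("geo", default_probe_geometry())

fx_bg <- function() optical_properties(rep(0.02, 4), 6)
fx_lesion <- function() optical_properties(rep(0.2, 4), 6)

fx_phantom <- function()
  tissue_phantom(fx_bg(), fx_lesion(), c(0.3, -0.2, 1.8), 0.8)

# noiseless single-repeat Born-mode measurement of the reference phantom,
# voxelised at the reconstruction fine-mesh pitch
fx_born_ms <- function() fixture("born_ms",
  simulate_measurements(fx_phantom(), fx_geometry(), n_repeats = 1,
                        probe_jitter_sd = 0, amp_noise_sd = 0,
                        phase_noise_sd_deg = 0, voxel_edge = 0.25,
                        scattering_model = "born"))

# small labelled cohort with default (rytov, noisy, jittered) acquisition
fx_cohort <- function() fixture("cohort", suppressWarnings(
  build_cohort(10, 10, seed = 301)))

# independent scalar evaluation of the semi-infinite Green's function:
# two-term image-source formula written out directly in R
oracle_green <- function(pa, pb, mua, musp, omega = 0) {
  d <- 1 / (3 * (mua + musp))
  k <- sqrt(complex(real = -mua, imaginary = omega / (2.99792458e10 / 1.33)) / d)
  if (Im(k) < 0) k <- -k
  zb <- 2 * d * (1 + 0.493) / (1 - 0.493)
  r1 <- sqrt(sum((pa - pb)^2))
  pi_img <- c(pa[1], pa[2], -pa[3] - 2 * zb)
  r2 <- sqrt(sum((pi_img - pb)^2))
  (exp(1i * k * r1) / r1 - exp(1i * k * r2) / r2) / (4 * pi * d)
}

# histogram centre of mass (distance of the binned mass from the origin)
hist_com_dist <- function(h) {
  rc <- (h$real_edges[-1] + h$real_edges[-length(h$real_edges)]) / 2
  ic <- (h$imag_edges[-1] + h$imag_edges[-length(h$imag_edges)]) / 2
  s <- sum(h$grid)
  sqrt(sum(colSums(h$grid) * rc)^2 + sum(rowSums(h$grid) * ic)^2) / s
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(abs(y)), tol)
}
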