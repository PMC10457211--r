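test_that("DC Green's function matches the two-term image-source formula", {
  props <- optical_properties(0.02, 6)
  pa <- c(0, 0, 0); pb <- c(2, 0, 0)
  g <- green_semi_infinite(pa, pb, props, modulation_frequency = 0)
  expect_equal(Im(g), 0)
  expect_gt(Re(g), 0)
  expect_equal(Re(g), Re(oracle_green(pa, pb, 0.02, 6)), tolerance = 1e-12)
  # off-boundary points, modulated
  pa2 <- c(0.5, -1, 0.3); pb2 <- c(-0.7, 0.2, 1.4)
  g2 <- green_semi_infinite(pa2, pb2, props, 140e6)
  o2 <- oracle_green(pa2, pb2, 0.02, 6, 2 * pi * 140e6)
  expect_lt(Mod(g2 - o2) / Mod(o2), 1e-12)
})

test_that("Green's function is reciprocal and monotone in absorption and distance", {
  props <- optical_properties(0.03, 7)
  pa <- c(0, 0, 0); pb <- c(1, 1, 1.5)
  expect_identical(green_semi_infinite(pa, pb, props),
                   green_semi_infinite(pb, pa, props))
  g1 <- green_semi_infinite(c(0, 0, 0), c(2, 0, 0),
                            optical_properties(0.02, 6), 0)
  g2 <- green_semi_infinite(c(0, 0, 0), c(2, 0, 0),
                            optical_properties(0.04, 6), 0)
  expect_lt(Mod(g2), Mod(g1))
  seps <- seq(0.2, 4, by = 0.2)
  mags <- vapply(seps, function(s)
    Mod(green_semi_infinite(c(0, 0, 0), c(s, 0, 0), props)), 0)
  expect_true(all(diff(mags) < 0))
})

test_that("Green's function rejects singular separations and bad properties", {
  props <- optical_properties(0.02, 6)
  expect_error(green_semi_infinite(c(0, 0, 0), c(0.05, 0, 0), props),
               "singularity")
  expect_error(optical_properties(-0.01, 6), "positive")
  expect_error(optical_properties(0.5, 0.4), "diffusion")
})

test_that("zero-contrast phantoms give exactly zero perturbation in both models", {
  bg <- fx_bg()
  ph <- suppressWarnings(
    tissue_phantom(bg, optical_properties(rep(0.02, 4), 6), c(0, 0, 1.5), 0.7))
  for (model in c("born", "rytov")) {
    ms <- simulate_measurements(ph, fx_geometry(), n_repeats = 2,
                                probe_jitter_sd = 0.25, amp_noise_sd = 0,
                                phase_noise_sd_deg = 0,
                                scattering_model = model, seed = 5)
    expect_true(all(compute_perturbation(ms)$values == 0))
  }
})

test_that("simulation is deterministic under seed and repeat-stable without noise", {
  ph <- fx_phantom()
  a <- simulate_measurements(ph, fx_geometry(), n_repeats = 2, seed = 42)
  b <- simulate_measurements(ph, fx_geometry(), n_repeats = 2, seed = 42)
  expect_identical(a$u_lesion, b$u_lesion)
  expect_identical(a$u_reference, b$u_reference)
  quiet <- simulate_measurements(ph, fx_geometry(), n_repeats = 2,
                                 probe_jitter_sd = 0, amp_noise_sd = 0,
                                 phase_noise_sd_deg = 0)
  expect_identical(quiet$u_lesion[, , , 1], quiet$u_lesion[, , , 2])
})

test_that("single-voxel Born field matches a hand-evaluated scatter term", {
  bg <- fx_bg()
  ctr <- c(0.4, -0.3, 1.6)
  ph <- suppressWarnings(tissue_phantom(bg, fx_lesion(), ctr, 0.05))
  geo <- fx_geometry()
  ms <- simulate_measurements(ph, geo, n_repeats = 1, probe_jitter_sd = 0,
                              amp_noise_sd = 0, phase_noise_sd_deg = 0,
                              voxel_edge = 0.1, scattering_model = "born")
  usc <- ms$u_lesion[, , 1, 1] - ms$u_reference[, , 1, 1]
  omega <- 2 * pi * geo$modulation_frequency
  d_coef <- 1 / (3 * (0.02 + 6))
  s <- 3; dt <- 7
  hand <- -oracle_green(geo$sources[s, ], ctr, 0.02, 6, omega) *
    oracle_green(ctr, geo$detectors[dt, ], 0.02, 6, omega) *
    (0.2 - 0.02) * 0.1^3 / d_coef
  expect_lt(Mod(usc[s, dt] - hand) / Mod(hand), 1e-10)
})

test_that("Born scattered field is exactly proportional to the contrast", {
  bg <- fx_bg()
  geo <- fx_geometry()
  mk <- function(mua) suppressWarnings(simulate_measurements(
    tissue_phantom(bg, optical_properties(rep(mua, 4), 6), c(0, 0, 1.6), 0.6),
    geo, n_repeats = 1, probe_jitter_sd = 0, amp_noise_sd = 0,
    phase_noise_sd_deg = 0, scattering_model = "born"))
  u1 <- mk(0.08); u2 <- mk(0.14)
  s1 <- u1$u_lesion - u1$u_reference
  s2 <- u2$u_lesion - u2$u_reference
  # contrasts 0.06 and 0.12: scattered field doubles exactly
  expect_equal(as.vector(s2), as.vector(2 * s1), tolerance = 1e-12)
})

test_that("rytov composition saturates where the linear field diverges", {
  ph <- suppressWarnings(tissue_phantom(
    optical_properties(rep(0.02, 4), 6), optical_properties(rep(0.3, 4), 6),
    c(0, 0, 1.6), 1.4))
  quiet <- function(model) simulate_measurements(
    ph, fx_geometry(), n_repeats = 1, probe_jitter_sd = 0,
    amp_noise_sd = 0, phase_noise_sd_deg = 0, scattering_model = model)
  pr <- compute_perturbation(quiet("rytov"))$values
  pb <- compute_perturbation(quiet("born"))$values
  # the lesion-side amplitude never exceeds the reference amplitude
  expect_true(all(Mod(1 + pr) <= 1 + 1e-9))
  expect_gt(min(Re(pr)), -2)
  # whereas the linear composition runs far out of the physical range
  expect_lt(min(Re(pb)), -2)
})

test_that("lesion intersecting the probe plane is rejected", {
  ph <- suppressWarnings(
    tissue_phantom(fx_bg(), fx_lesion(), c(0, 0, 0.5), 0.8))
  expect_error(simulate_measurements(ph, fx_geometry()), "intersects")
})

test_that("sampled phantoms respect the cohort parameter ranges", {
  phs <- lapply(seq_len(10000), function(i)
    sample_phantom(if (i %% 2) "benign" else "malignant", seed = i))
  r <- vapply(phs, `[[`, 0, "lesion_radius")
  z <- vapply(phs, function(p) p$lesion_center[3], 0)
  lm <- vapply(phs, function(p) p$lesion$mua[1], 0)
  bm <- vapply(phs, function(p) p$background$mua[1], 0)
  sc <- vapply(phs, function(p) p$lesion$musp[1], 0)
  expect_true(all(r >= 0.375 & r <= 1.5))
  expect_true(all(z >= 0.7 & z <= 2.7))
  expect_true(all(lm >= 0.06 & lm <= 0.30))
  expect_true(all(bm >= 0.01 & bm <= 0.06))
  expect_true(all(sc >= 4 & sc <= 8))
  expect_true(all(z > r))  # sphere below the probe plane
})

test_that("phantom sampling is seeded and class contrasts are ordered", {
  expect_identical(sample_phantom("malignant", seed = 7),
                   sample_phantom("malignant", seed = 7))
  ben <- vapply(1:1000, function(i)
    sample_phantom("benign", seed = i)$lesion$mua[1], 0)
  mal <- vapply(1:1000, function(i)
    sample_phantom("malignant", seed = 10000 + i)$lesion$mua[1], 0)
  expect_lt(mean(ben), mean(mal))
  # class-conditional size: malignant lesions are larger on average
  benr <- vapply(1:500, function(i)
    sample_phantom("benign", seed = i)$lesion_radius, 0)
  malr <- vapply(1:500, function(i)
    sample_phantom("malignant", seed = 10000 + i)$lesion_radius, 0)
  expect_lt(mean(benr), mean(malr))
})
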