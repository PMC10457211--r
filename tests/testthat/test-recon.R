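one_voxel_mesh <- function(center, edge = 0.1) {
  structure(list(centers = matrix(center, 1), volumes = edge^3,
                 n_fine = 1L, fine_edge = rep(edge, 3),
                 roi = list(center = center, radius = edge),
                 domain = c(9, 9, 5)), class = "dual_mesh")
}

test_that("sensitivity matrix reproduces the forward scattered field", {
  ctr <- c(0.4, -0.3, 1.6)
  ph <- suppressWarnings(tissue_phantom(fx_bg(), fx_lesion(), ctr, 0.05))
  ms <- simulate_measurements(ph, fx_geometry(), n_repeats = 1,
                              probe_jitter_sd = 0, amp_noise_sd = 0,
                              phase_noise_sd_deg = 0, voxel_edge = 0.1,
                              scattering_model = "born")
  w <- assemble_sensitivity(fx_geometry(), fx_bg(), one_voxel_mesh(ctr), 1)
  pred <- w$w %*% (0.2 - 0.02)
  truth <- as.vector(ms$u_lesion[, , 1, 1] / ms$u_reference[, , 1, 1] - 1)
  expect_lt(max(Mod(pred - truth)) / max(Mod(truth)), 1e-10)
})

test_that("sensitivity entries are finite, nonzero and linear in volume", {
  mesh <- build_dual_mesh(c(0, 0, 1.8), 0.6)
  w <- assemble_sensitivity(fx_geometry(), fx_bg(), mesh, 2)
  expect_true(all(is.finite(Re(w$w))) && all(is.finite(Im(w$w))))
  expect_true(all(Mod(w$w) > 0))
  mesh2 <- mesh; mesh2$volumes <- 2 * mesh$volumes
  w2 <- assemble_sensitivity(fx_geometry(), fx_bg(), mesh2, 2)
  expect_equal(w2$w, 2 * w$w, tolerance = 1e-12)
})

test_that("CG solves the identity and ridge closed forms", {
  sol <- solve_cg(diag(5), c(1, 0, 0, 0, 0), recon_config(lambda = 0))
  expect_equal(sol$delta_mua, c(1, 0, 0, 0, 0), tolerance = 1e-10)
  p <- c(0.4, -0.2, 0.7, 0.1, -0.5)
  sol2 <- solve_cg(diag(5), p, recon_config(lambda = 1))
  expect_equal(sol2$delta_mua, p / 2, tolerance = 1e-10)
})

test_that("CG matches the dense ridge solution on random systems", {
  set.seed(31)
  for (dims in list(c(40, 25, 0.3), c(120, 80, 0.05), c(300, 500, 0.2))) {
    a <- matrix(rnorm(dims[1] * dims[2]), dims[1])
    b <- rnorm(dims[1])
    lam <- dims[3]
    sol <- solve_cg(a, b, recon_config(lambda = lam, max_iterations = 2000,
                                       tol = 1e-14))
    direct <- solve(crossprod(a) + lam^2 * diag(ncol(a)), crossprod(a, b))
    expect_rel_equal(sol$delta_mua, as.numeric(direct), 1e-6)
  }
  # complex stacked system
  a <- matrix(complex(real = rnorm(600), imaginary = rnorm(600)), 30)
  b <- complex(real = rnorm(30), imaginary = rnorm(30))
  sol <- solve_cg(a, b, recon_config(lambda = 0.4, max_iterations = 1000,
                                     tol = 1e-14))
  ar <- rbind(Re(a), Im(a)); br <- c(Re(b), Im(b))
  direct <- solve(crossprod(ar) + 0.16 * diag(20), crossprod(ar, br))
  expect_rel_equal(sol$delta_mua, as.numeric(direct), 1e-6)
})

test_that("objective is non-increasing and shrinks monotonically with lambda", {
  set.seed(32)
  a <- matrix(rnorm(60 * 40), 60); b <- rnorm(60)
  sol <- solve_cg(a, b, recon_config(lambda = 0.2, max_iterations = 50))
  expect_true(all(diff(sol$objective) <= 1e-8))
  norms <- vapply(c(0.01, 0.1, 0.5, 1, 5, 20), function(l)
    sqrt(sum(solve_cg(a, b, recon_config(lambda = l))$delta_mua^2)), 0)
  expect_true(all(diff(norms) < 0))
})

test_that("CG rejects mismatched dimensions", {
  expect_error(solve_cg(diag(4), c(1, 0, 0)), "length")
})

test_that("haemoglobin unmixing round-trips exactly", {
  ext <- hb_extinction()
  set.seed(33)
  conc <- cbind(hbo2 = runif(50, 10, 60), hb = runif(50, 5, 40))
  mua <- conc %*% t(ext)           # voxels x wavelengths
  bg <- as.numeric(ext %*% c(10, 8))
  un <- unmix_thb(sweep(mua, 2, bg), bg, ext)
  expect_rel_equal(un$hbo2, conc[, 1], 1e-8)
  expect_rel_equal(un$hb, conc[, 2], 1e-8)
  expect_rel_equal(un$thb, rowSums(conc), 1e-8)
  # homogeneous: zero contrast gives uniform background tHb
  un0 <- unmix_thb(matrix(0, 5, 4), bg, ext)
  expect_equal(un0$thb, rep(18, 5), tolerance = 1e-10)
  # linearity: doubling mua doubles tHb
  un2 <- unmix_thb(sweep(2 * mua, 2, 2 * bg), 2 * bg, ext)
  expect_rel_equal(un2$thb, 2 * un$thb, 1e-10)
})

test_that("rank-deficient extinction tables are rejected", {
  bad <- data.frame(wavelength = c(740, 780, 808, 830),
                    hbo2 = c(1, 2, 3, 4), hb = c(2, 4, 6, 8))
  expect_error(hb_extinction(table = bad), "rank")
  expect_error(hb_extinction(c(740, 999)), "999")
})

test_that("tHb rendering is a faithful nearest-voxel resampler", {
  mesh <- build_dual_mesh(c(0, 0, 2), 0.8)
  img <- render_thb_image(rep(7, nrow(mesh$centers)), mesh)
  expect_identical(dim(thb_image(img)), c(32L, 32L, 3L))
  expect_true(all(thb_image(img) == 7))
  # single hot fine voxel: the maximum pixel sits nearest that voxel
  v <- rep(0, nrow(mesh$centers))
  hot <- which.min(rowSums(sweep(mesh$centers, 2, c(0.6, -0.9, 2))^2))
  v[hot] <- 50
  img2 <- thb_image(render_thb_image(v, mesh))
  k <- which(img2 == max(img2), arr.ind = TRUE)[1, ]
  px <- attr(render_thb_image(v, mesh), "pixel_pitch")
  pos <- c(-4.5 + (k[1] - 0.5) * px, -4.5 + (k[2] - 0.5) * px)
  expect_lt(sqrt(sum((pos - mesh$centers[hot, 1:2])^2)), px * 1.5)
  # negatives are clamped
  img3 <- thb_image(render_thb_image(rep(-3, nrow(mesh$centers)), mesh))
  expect_true(all(img3 == 0))
})

test_that("the Born-consistent inverse crime closes", {
  ph <- fx_phantom()
  ms <- fx_born_ms()  # noiseless, jitter-free, voxelised at 0.25 cm
  mesh <- build_dual_mesh(ph$lesion_center, ph$lesion_radius)
  # small lambda relative to the operator norm
  w <- assemble_sensitivity(fx_geometry(), fx_bg(), mesh, 1)
  wv <- sweep(w$w, 2, mesh$volumes, "/")
  a <- rbind(Re(wv), Im(wv))
  smax <- svd(a, nu = 0, nv = 0)$d[1]
  rec <- reconstruct_thb(ms, ph$lesion_center, ph$lesion_radius, fx_bg(),
                         recon_config(lambda = 1e-3 * smax,
                                      max_iterations = 300, tol = 1e-10),
                         linearization = "born")
  truth <- 0.2 - 0.02
  for (wl in 1:4) {
    dm <- rec$delta_mua[, wl]
    peak <- which.max(dm)
    expect_lt(abs(dm[peak] - truth) / truth, 0.2)
    expect_lt(sqrt(sum((rec$mesh$centers[peak, ] - ph$lesion_center)^2)),
              max(rec$mesh$fine_edge) + 1e-9)
  }
})

test_that("regularisation strength controls reconstruction smoothness", {
  ph <- fx_phantom()
  ms <- fx_born_ms()
  rec_small <- reconstruct_thb(ms, ph$lesion_center, ph$lesion_radius,
                               fx_bg(), recon_config(lambda = 1e-4,
                                                     max_iterations = 100,
                                                     tol = 1e-8),
                               linearization = "born")
  rec_big <- reconstruct_thb(ms, ph$lesion_center, ph$lesion_radius,
                             fx_bg(), recon_config(lambda = 10,
                                                   max_iterations = 100,
                                                   tol = 1e-8),
                             linearization = "born")
  expect_gt(max(rec_small$delta_mua), max(rec_big$delta_mua))
})
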