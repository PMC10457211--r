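fake_ms <- function(ul, ur) {
  structure(list(u_lesion = ul, u_reference = ur), class = "measurement_set")
}

test_that("perturbation has the closed forms for simple ratios", {
  ur <- array(complex(real = rnorm(24), imaginary = rnorm(24)), c(2, 3, 2, 2))
  expect_true(all(compute_perturbation(fake_ms(ur, ur))$values == 0))
  p <- compute_perturbation(fake_ms(0.5 * ur, ur))$values
  expect_equal(p, rep(complex(real = -0.5), 24), tolerance = 1e-12)
  p2 <- compute_perturbation(fake_ms((1 + 1i) * ur, ur))$values
  expect_equal(p2, rep(complex(imaginary = 1), 24), tolerance = 1e-12)
})

test_that("a zero reference entry is reported with its index", {
  ur <- array(complex(real = 1), c(2, 2, 2, 2))
  ur[2, 1, 2, 1] <- 0
  expect_error(compute_perturbation(fake_ms(ur, ur)),
               "source 2, detector 1, wavelength 2, repeat 1")
})

test_that("histogram mass equals sources x detectors x wavelengths x repeats", {
  ms <- simulate_measurements(fx_phantom(), fx_geometry(), n_repeats = 3,
                              seed = 9)
  p <- compute_perturbation(ms)
  expect_length(p$values, 9 * 14 * 4 * 3)
  h <- build_histogram(p)
  expect_identical(dim(h$grid), c(32L, 32L))
  expect_equal(h$n_points, 1512)
  # clipping conserves mass: raw total equals the point count
  expect_equal(sum(h$grid) * h$divisor, 1512, tolerance = 1e-12)
  expect_equal(h$divisor, 1 * 4 * 14)
})

test_that("a single point lands in exactly one bin", {
  p <- structure(list(values = complex(real = -0.5, imaginary = 0),
                      n_sources = 1, n_detectors = 1, n_wavelengths = 1,
                      n_repeats = 1), class = "perturbation")
  h <- build_histogram(p)
  expect_equal(sum(h$grid != 0), 1)
  expect_equal(sum(h$grid) * h$divisor, 1)
  hit <- which(h$grid != 0, arr.ind = TRUE)
  # bin edges are half-open [lo, hi): -0.5 sits at the left edge of its
  # real bin, 0 at the left edge of its imaginary bin
  expect_true(h$real_edges[hit[2]] <= -0.5 && -0.5 < h$real_edges[hit[2] + 1])
  expect_true(h$imag_edges[hit[1]] <= 0 && 0 < h$imag_edges[hit[1] + 1])
})

test_that("binning matches a brute-force oracle and divides by the divisor", {
  set.seed(14)
  v <- complex(real = rnorm(200, sd = 0.8), imaginary = rnorm(200, sd = 0.8))
  p <- structure(list(values = v, n_sources = 10, n_detectors = 5,
                      n_wavelengths = 2, n_repeats = 2),
                 class = "perturbation")
  h <- build_histogram(p, real_range = c(-1, 1), imag_range = c(-1, 1))
  # brute-force loop oracle with clipping to edge bins
  grid <- matrix(0, 32, 32)
  edges <- seq(-1, 1, length.out = 33)
  for (z in v) {
    jr <- 32; ji <- 32
    re <- min(max(Re(z), -1), 1); im <- min(max(Im(z), -1), 1)
    for (b in 1:32) {
      if (re >= edges[b] && (re < edges[b + 1] || b == 32)) jr <- b
      if (im >= edges[b] && (im < edges[b + 1] || b == 32)) ji <- b
    }
    grid[ji, jr] <- grid[ji, jr] + 1
  }
  expect_equal(h$grid * h$divisor, grid, tolerance = 1e-12)
  expect_equal(h$divisor, 1 * 2 * 5)
})

test_that("histograms are invariant to point order and pool multiple files", {
  set.seed(15)
  mk <- function(v) structure(list(values = v, n_sources = 4,
                                   n_detectors = 3, n_wavelengths = 2,
                                   n_repeats = 1), class = "perturbation")
  v <- complex(real = runif(60, -1, 1), imaginary = runif(60, -1, 1))
  h1 <- build_histogram(mk(v))
  h2 <- build_histogram(mk(sample(v)))
  expect_identical(h1$grid, h2$grid)
  hp <- build_histogram(list(mk(v[1:24]), mk(v[25:48])))
  expect_equal(hp$divisor, 2 * 2 * 3)
  expect_equal(sum(hp$grid) * hp$divisor, 48, tolerance = 1e-12)
})

test_that("optional magnitude filter drops outliers, empty input errors", {
  p <- structure(list(values = c(0.1 + 0i, 3 + 0i), n_sources = 2,
                      n_detectors = 1, n_wavelengths = 1, n_repeats = 1),
                 class = "perturbation")
  h <- build_histogram(p, magnitude_filter = 2)
  expect_equal(h$n_points, 1)
  expect_error(build_histogram(list()), "no perturbations")
})

test_that("benign histograms centre nearer the origin than malignant ones", {
  n <- 50
  dist_for <- function(label, seeds) vapply(seeds, function(s) {
    ph <- sample_phantom(label, seed = s)
    ms <- simulate_measurements(ph, fx_geometry(), n_repeats = 1,
                                seed = s + 1)
    hist_com_dist(build_histogram(compute_perturbation(ms)))
  }, 0)
  ben <- dist_for("benign", 1:n)
  mal <- dist_for("malignant", 5000 + 1:n)
  expect_lt(mean(ben), mean(mal))
})
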