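test_that("cohorts are labelled, complete and deterministic", {
  co <- fx_cohort()
  expect_length(co, 20)
  expect_equal(sum(cohort_labels(co) == "benign"), 10)
  expect_false(anyDuplicated(cohort_ids(co)) > 0)
  for (cs in co[c(1, 15)]) {
    expect_identical(dim(cs$histogram$grid), c(32L, 32L))
    expect_gt(sum(cs$histogram$grid), 0)
    expect_identical(dim(cs$measurements$u_lesion)[1:3], c(9L, 14L, 4L))
    expect_identical(cs$label == "malignant",
                     cs$phantom$lesion$mua[1] > 0.15)
  }
  co2 <- suppressWarnings(build_cohort(10, 10, seed = 301))
  expect_identical(co[[7]]$measurements$u_lesion,
                   co2[[7]]$measurements$u_lesion)
  expect_identical(case_us_image(co[[3]])$image,
                   case_us_image(co2[[3]])$image)
})

test_that("a linear read-out of the perturbation separates the classes", {
  co <- suppressWarnings(build_cohort(60, 60, seed = 311))
  y <- as.integer(cohort_labels(co) == "malignant")
  x <- vapply(co, function(cs)
    mean(Re(compute_perturbation(cs$measurements)$values)), 0)
  set.seed(312)
  idx <- sample(120)
  tr <- idx[1:80]; te <- idx[81:120]
  fit <- stats::glm(y[tr] ~ x[tr], family = stats::binomial())
  p <- stats::plogis(cbind(1, x[te]) %*% stats::coef(fit))
  expect_gt(roc_auc(as.numeric(p), y[te])$auc, 0.8)
})

test_that("bootstrap splits are balanced, disjoint and reproducible", {
  labels <- rep(c("benign", "malignant"), c(100, 90))
  names(labels) <- sprintf("c%03d", seq_along(labels))
  sp <- make_bootstrap_splits(labels, n_runs = 10, seed = 9)
  expect_length(sp, 10)
  for (s in sp) {
    expect_length(s$train_ids, 120)
    expect_length(s$test_ids, 50)
    expect_length(intersect(s$train_ids, s$test_ids), 0)
    expect_equal(sum(labels[s$train_ids] == "benign"), 60)
    expect_equal(sum(labels[s$test_ids] == "malignant"), 25)
  }
  sp2 <- make_bootstrap_splits(labels, n_runs = 10, seed = 9)
  expect_identical(sp, sp2)
  expect_false(identical(sp[[1]]$train_ids, sp[[2]]$train_ids))
  expect_error(make_bootstrap_splits(labels[1:100], n_runs = 2, seed = 1),
               "at least")
})

test_that("measurement sets and histograms round-trip through plain text", {
  co <- fx_cohort()
  ms <- co[[2]]$measurements
  path <- file.path(tempdir(), "ms_roundtrip")
  write_measurement_set(ms, path)
  ms2 <- read_measurement_set(path)
  expect_identical(ms$u_lesion, ms2$u_lesion)
  expect_identical(ms$u_reference, ms2$u_reference)
  expect_equal(ms$geometry$sources, ms2$geometry$sources,
               tolerance = 1e-12)
  expect_identical(ms$wavelengths, ms2$wavelengths)
  h <- co[[2]]$histogram
  hp <- file.path(tempdir(), "hist_roundtrip")
  write_histogram(h, hp)
  h2 <- read_histogram(hp)
  expect_identical(h$grid, h2$grid)
  expect_identical(h$divisor, h2$divisor)
  man <- cohort_manifest(co)
  expect_identical(nrow(man), 20L)
  expect_true(all(c("case_id", "label", "lesion_radius") %in% names(man)))
})
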