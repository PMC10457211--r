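# mean gradient magnitude on the lesion contour: the margin-sharpness
# statistic a margin-based classifier keys on
contour_sharpness <- function(us) {
  m <- us$mask
  n <- nrow(m)
  inner <- m[2:(n - 1), 2:(n - 1)]
  ring <- inner & !(m[1:(n - 2), 2:(n - 1)] & m[3:n, 2:(n - 1)] &
                      m[2:(n - 1), 1:(n - 2)] & m[2:(n - 1), 3:n])
  gx <- us$image[3:n, 2:(n - 1)] - us$image[1:(n - 2), 2:(n - 1)]
  gy <- us$image[2:(n - 1), 3:n] - us$image[2:(n - 1), 1:(n - 2)]
  mean(sqrt(gx[ring]^2 + gy[ring]^2))
}

test_that("ultrasound surrogates are deterministic and ROI-consistent", {
  a <- generate_us_image("malignant", 0.8, seed = 50)
  b <- generate_us_image("malignant", 0.8, seed = 50)
  expect_identical(a$image, b$image)
  for (us in list(a, generate_us_image("benign", 0.5, seed = 51))) {
    rows <- range(which(rowSums(us$mask) > 0))
    cols <- range(which(colSums(us$mask) > 0))
    expect_true(us$roi[1] <= rows[1] && us$roi[2] >= rows[2])
    expect_true(us$roi[3] <= cols[1] && us$roi[4] >= cols[2])
    expect_true(all(us$image >= 0 & us$image <= 1))
  }
})

test_that("benign margins are sharper than malignant margins", {
  sharp <- vapply(1:40, function(s) {
    r <- 0.5 + 0.4 * (s %% 5) / 5
    c(contour_sharpness(generate_us_image("benign", r, seed = 600 + s)),
      contour_sharpness(generate_us_image("malignant", r, seed = 700 + s)))
  }, numeric(2))
  expect_gt(mean(sharp[1, ]), mean(sharp[2, ]))
})

test_that("oversized lesions are rejected", {
  expect_error(generate_us_image("benign", 1.5, pixel_pitch = 0.044),
               "field of view")
})

test_that("preprocessing produces normalised 224 x 224 x 3 arrays", {
  us <- generate_us_image("benign", 0.6, seed = 52)
  x <- preprocess_us(us)
  expect_identical(dim(x), c(224L, 224L, 3L))
  # constant ROI: each channel collapses to its normalisation constant
  flat <- us; flat$image[] <- 0.5
  xf <- preprocess_us(flat)
  mu <- c(0.485, 0.456, 0.406); sdv <- c(0.229, 0.224, 0.225)
  for (c in 1:3)
    expect_equal(unique(as.vector(xf[, , c])), (0.5 - mu[c]) / sdv[c],
                 tolerance = 1e-9)
})

test_that("a 224-pixel crop passes through resizing unchanged", {
  set.seed(53)
  img <- matrix(runif(300 * 300), 300)
  roi <- c(10, 233, 20, 243)  # exactly 224 x 224
  x <- preprocess_us(img, roi)
  manual <- (img[10:233, 20:243] - 0.485) / 0.229
  expect_equal(x[, , 1], manual, tolerance = 1e-9)
  expect_error(preprocess_us(img, c(50, 40, 1, 10)), "ROI")
})
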