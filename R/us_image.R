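#' Synthetic B-mode-style ultrasound lesion image
#'
#' Surrogate grayscale ultrasound image: multiplicative speckle texture
#' with a hypoechoic lesion. Benign lesions render as smooth ellipses
#' with a sharp margin; malignant lesions get an irregular boundary
#' (low-order random radial harmonics), a blurred, ill-defined margin and
#' mild posterior shadowing. This gives a classifier the same
#' margin-sharpness cue radiologists use, without claiming clinical
#' realism. The ROI box is the lesion bounding box padded by 20%.
#'
#' @param label "benign" or "malignant".
#' @param lesion_radius Radius, cm.
#' @param lesion_depth Centre depth, cm (cosmetic only; the lesion is
#'   rendered at the image centre).
#' @param pixel_pitch Pixel size, mm.
#' @param seed Integer seed; images are a pure function of it.
#' @return Object of class `us_image`: `image` (matrix in `[0, 1]`),
#'   `roi` `c(row0, row1, col0, col1)`, the lesion `mask`, `pixel_pitch`
#'   and `label`.
#' @export
generate_us_image <- function(label = c("benign", "malignant"),
                              lesion_radius, lesion_depth = NULL,
                              pixel_pitch = 0.1, seed = NULL) {
  label <- match.arg(label)
  stopifnot(lesion_radius > 0, pixel_pitch > 0)
  if (!is.null(seed)) set.seed(seed)
  rpx <- lesion_radius * 10 / pixel_pitch
  n <- min(640L, max(160L, as.integer(round(4.2 * rpx))))
  if (2 * rpx * 1.3 > n)
    stop("lesion larger than the simulated field of view")
  # speckle: exponentiated smoothed gaussian noise
  sp <- EBImage::gblur(matrix(rnorm(n * n), n, n), sigma = 1.2)
  img <- 0.45 * exp(0.9 * sp / stats::sd(sp))
  img <- img / mean(img) * 0.45
  # lesion boundary radius as a function of polar angle
  cx <- n / 2 + 0.5
  row <- matrix(seq_len(n), n, n)
  col <- matrix(seq_len(n), n, n, byrow = TRUE)
  dy <- row - cx; dx <- col - cx
  th <- atan2(dy, dx)
  phi <- runif(1, 0, pi)
  ab <- runif(1, 0.65, 0.95)
  # ellipse radius at angle th (axes rpx and ab*rpx, rotated by phi)
  ct <- cos(th - phi); st <- sin(th - phi)
  rb <- rpx * ab / sqrt(ab^2 * ct^2 + st^2)
  if (label == "malignant") {
    nlobe <- sample(3:8, 1)
    amp <- runif(1, 0.12, 0.25)
    ph2 <- runif(1, 0, 2 * pi)
    rb <- rb * (1 + amp * cos(nlobe * th + ph2) +
                  0.5 * amp * cos((nlobe + 2) * th - ph2))
  }
  rr <- sqrt(dx^2 + dy^2)
  mask <- rr <= rb
  # attenuation map: darker interior, sharp for benign, blurred and
  # heterogeneous for malignant
  att <- matrix(1, n, n)
  att[mask] <- 0.32
  if (label == "malignant") {
    att <- EBImage::gblur(att, sigma = max(2, 0.12 * rpx))
    het <- EBImage::gblur(matrix(rnorm(n * n), n, n), sigma = 4)
    att <- att * (1 + 0.15 * het / stats::sd(het) * (rr <= 1.2 * rb))
    # posterior shadowing below the lesion
    shadow <- matrix(1, n, n)
    for (j in seq_len(n)) {
      ms <- which(mask[, j])
      if (length(ms)) shadow[max(ms):n, j] <- 0.8
    }
    att <- att * EBImage::gblur(shadow, sigma = 3)
  }
  img <- pmin(pmax(img * att, 0), 1)
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  pad_r <- ceiling(0.2 * diff(rows)); pad_c <- ceiling(0.2 * diff(cols))
  roi <- c(max(1, rows[1] - pad_r), min(n, rows[2] + pad_r),
           max(1, cols[1] - pad_c), min(n, cols[2] + pad_c))
  structure(list(image = img, roi = roi, mask = mask,
                 pixel_pitch = pixel_pitch, label = label),
            class = "us_image")
}

#' Preprocess an ultrasound image for the US CNN branch
#'
#' Crops to the ROI, bilinearly resizes to 224 x 224, replicates to three
#' channels and standardises each channel with the fixed natural-image
#' corpus statistics (means 0.485/0.456/0.406, SDs 0.229/0.224/0.225).
#'
#' @param us A `us_image`, or a plain matrix plus `roi`.
#' @param roi ROI `c(row0, row1, col0, col1)` when `us` is a matrix.
#' @return Numeric array dim (224, 224, 3).
#' @export
preprocess_us <- function(us, roi = NULL) {
  if (inherits(us, "us_image")) { roi <- us$roi; us <- us$image }
  if (is.null(roi)) stop("an ROI is required")
  if (roi[1] > roi[2] || roi[3] > roi[4]) stop("empty ROI")
  crop <- us[roi[1]:roi[2], roi[3]:roi[4], drop = FALSE]
  if (!length(crop)) stop("empty ROI")
  res <- if (all(dim(crop) == c(224L, 224L))) crop else
    EBImage::resize(crop, w = 224, h = 224)
  res <- matrix(as.numeric(res), 224, 224)
  mu <- c(0.485, 0.456, 0.406); sdv <- c(0.229, 0.224, 0.225)
  out <- array(0, c(224, 224, 3))
  for (c in 1:3) out[, , c] <- (res - mu[c]) / sdv[c]
  out
}
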