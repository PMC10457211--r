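#' First-stage triage decision
#'
#' Averages the US-branch and histogram-branch malignancy probabilities;
#' cases with averaged probability strictly below the threshold are
#' called benign, all others suspicious (a boundary case counts as
#' suspicious).
#'
#' @param p_us,p_hist Probabilities in `[0, 1]` (vectors allowed).
#' @param threshold Triage threshold in `[0, 0.5)`.
#' @return Data frame with `p_us`, `p_hist`, `p_avg`, `threshold` and
#'   `decision` ("benign"/"suspicious").
#' @export
stage1_predict <- function(p_us, p_hist, threshold) {
  if (any(p_us < 0 | p_us > 1) || any(p_hist < 0 | p_hist > 1))
    stop("probabilities must lie in [0, 1]")
  if (threshold < 0 || threshold >= 0.5)
    stop("threshold must lie in [0, 0.5)")
  p_avg <- (p_us + p_hist) / 2
  data.frame(p_us = p_us, p_hist = p_hist, p_avg = p_avg,
             threshold = threshold,
             decision = ifelse(p_avg < threshold, "benign", "suspicious"),
             stringsAsFactors = FALSE)
}

#' Grid search of the triage threshold
#'
#' Evaluates thresholds 0.01, 0.02, ..., 0.49 on training-set stage-1
#' scores and returns, among thresholds achieving the minimum false-
#' negative rate (fraction of malignant cases called benign), the
#' largest one — which maximises the benign yield at that
#' false-negative cost.
#'
#' @param scores Stage-1 averaged probabilities.
#' @param labels Case labels (benign/malignant, factor, or 0/1).
#' @return The selected threshold.
#' @export
grid_search_threshold <- function(scores, labels) {
  y <- as_label(labels)
  if (length(unique(y)) < 2L) stop("both classes are required")
  grid <- seq(0.01, 0.49, by = 0.01)
  fn_rate <- vapply(grid, function(t) mean(scores[y == 1] < t), 0)
  cand <- which(fn_rate == min(fn_rate))
  grid[max(cand)]
}

#' Run the two-stage classification on a set of cases
#'
#' Stage 1 scores every case from its ultrasound image and DOT histogram
#' and calls cases below the threshold benign. Only the remaining
#' suspicious cases are reconstructed (via `recon_fn`), featurised, and
#' classified by the fusion head. Final scores are the stage-1 average
#' for stage-1-benign cases and the fusion probability otherwise; final
#' labels cut the stage-2 probability at 0.5.
#'
#' @param cases List of `synthetic_case` objects.
#' @param models List with elements `us`, `hist`, `img`, `fusion`
#'   (trained branches/head).
#' @param threshold Stage-1 threshold in `[0, 0.5)`.
#' @param recon_fn Function `(case) -> thb_map` (or 32 x 32 x 3 array);
#'   called exactly once per suspicious case.
#' @param us_feats Optional cached (7, 7, 512, N) US backbone features
#'   aligned with `cases`; without them images are rendered and passed
#'   through the full branch.
#' @return Data frame (one row per case) with stage-1 fields, `p_stage2`
#'   (NA for stage-1-benign cases), `final_score` and `final_label`;
#'   attribute `n_recon_calls` counts reconstructions.
#' @export
run_two_stage <- function(cases, models, threshold, recon_fn,
                          us_feats = NULL) {
  n <- length(cases)
  if (is.null(us_feats)) {
    p_us <- vapply(cases, function(cs)
      nn_predict(models$us, preprocess_us(case_us_image(cs))), 0)
  } else {
    p_us <- us_head_predict(models$us, us_feats)
  }
  p_hist <- nn_predict(models$hist,
                       histogram_input(lapply(cases, `[[`, "histogram")))
  s1 <- stage1_predict(p_us, p_hist, threshold)
  susp <- which(s1$decision == "suspicious")
  p2 <- rep(NA_real_, n)
  n_recon <- 0L
  if (length(susp)) {
    thb <- array(0, c(32, 32, 3, length(susp)))
    for (k in seq_along(susp)) {
      thb[, , , k] <- thb_image(recon_fn(cases[[susp[k]]]))
      n_recon <- n_recon + 1L
    }
    if (isTRUE(models$fusion$fallback)) {
      p2[susp] <- s1$p_avg[susp]
    } else {
      f_us <- if (is.null(us_feats)) {
        imgs <- array(0, c(224, 224, 3, length(susp)))
        for (k in seq_along(susp))
          imgs[, , , k] <- preprocess_us(case_us_image(cases[[susp[k]]]))
        extract_features(models$us, imgs)
      } else {
        us_head_features(models$us, us_feats[, , , susp, drop = FALSE])
      }
      f_hist <- extract_features(models$hist,
        histogram_input(lapply(cases[susp], `[[`, "histogram")))
      f_img <- extract_features(models$img, thb)
      p2[susp] <- nn_predict(models$fusion, fuse_features(f_us, f_hist, f_img))
    }
  }
  final_score <- ifelse(is.na(p2), s1$p_avg, p2)
  final_label <- ifelse(s1$decision == "benign", "benign",
                        ifelse(p2 >= 0.5, "malignant", "benign"))
  out <- data.frame(case_id = cohort_ids(cases),
                    label = cohort_labels(cases),
                    s1, p_stage2 = p2, final_score = final_score,
                    final_label = final_label, stringsAsFactors = FALSE)
  attr(out, "n_recon_calls") <- n_recon
  out
}

#' Combined two-stage confusion counts
#'
#' Stage 1 contributes only benign calls (true benign `tb1`, false
#' benign `fb1`); stage 2 contributes the four cells of its own
#' confusion (`tm2`, `fm2`, `fb2`, `tb2`). The six cells always sum to
#' the number of test cases.
#'
#' @param results Output of [run_two_stage()].
#' @param labels Optional truth labels (defaults to `results$label`).
#' @return Named list of the six counts.
#' @export
combined_confusion <- function(results, labels = results$label) {
  if (length(labels) != nrow(results))
    stop("labels length does not match results")
  y <- as_label(labels)
  s1_benign <- results$decision == "benign"
  pred_mal <- results$final_label == "malignant"
  list(tm2 = sum(!s1_benign & pred_mal & y == 1),
       fm2 = sum(!s1_benign & pred_mal & y == 0),
       fb1 = sum(s1_benign & y == 1),
       fb2 = sum(!s1_benign & !pred_mal & y == 1),
       tb1 = sum(s1_benign & y == 0),
       tb2 = sum(!s1_benign & !pred_mal & y == 0))
}

#' ROC curve and AUC by threshold sweep
#'
#' Trapezoidal AUC with tied scores handled as simultaneous steps
#' (equivalently, the Mann-Whitney pairwise concordance with ties
#' counted 1/2).
#'
#' @param scores Final scores, higher = more malignant.
#' @param labels Truth labels.
#' @return List with `auc` and a data frame `curve` (fpr, tpr).
#' @export
roc_auc <- function(scores, labels) {
  y <- as_label(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: a single class is present")
  r <- rank(scores)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(scores[y == 1] >= t), 0)
  fpr <- vapply(th, function(t) mean(scores[y == 0] >= t), 0)
  list(auc = auc,
       curve = data.frame(threshold = c(Inf, th), fpr = c(0, fpr),
                          tpr = c(0, tpr)))
}

#' Single-stage fusion baseline
#'
#' Reconstructs and featurises every test case (no triage) and scores
#' all of them with a fusion head, the comparison arm for the two-stage
#' strategy.
#'
#' @param cases Test cases.
#' @param models List with `us`, `hist`, `img`, `fusion` (the fusion
#'   head trained on all training cases).
#' @param recon_fn Reconstruction function `(case) -> thb_map`.
#' @param us_feats Optional cached US backbone features.
#' @return List with `auc`, per-case `scores`, and `n_recon_calls`.
#' @export
single_stage_baseline <- function(cases, models, recon_fn, us_feats = NULL) {
  n <- length(cases)
  thb <- array(0, c(32, 32, 3, n))
  for (k in seq_len(n)) thb[, , , k] <- thb_image(recon_fn(cases[[k]]))
  f_us <- if (is.null(us_feats)) {
    imgs <- array(0, c(224, 224, 3, n))
    for (k in seq_len(n))
      imgs[, , , k] <- preprocess_us(case_us_image(cases[[k]]))
    extract_features(models$us, imgs)
  } else us_head_features(models$us, us_feats)
  f_hist <- extract_features(models$hist,
    histogram_input(lapply(cases, `[[`, "histogram")))
  f_img <- extract_features(models$img, thb)
  scores <- nn_predict(models$fusion, fuse_features(f_us, f_hist, f_img))
  list(auc = roc_auc(scores, cohort_labels(cases))$auc, scores = scores,
       n_recon_calls = n)
}
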