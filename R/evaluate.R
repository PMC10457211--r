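# reconstruction provider with per-context call counting and a cache, so
# a case reconstructed for one purpose is not recomputed for another
# while call counts per context stay exact

#' Counting, caching reconstruction provider
#'
#' Wraps the US-guided reconstruction so the two-stage pipeline can be
#' audited: every request is counted under a context tag, while the
#' underlying reconstruction runs at most once per case.
#'
#' @param config A [recon_config()].
#' @return List with `fn(case, context)`, `counts()` (requests per
#'   context), and `n_computed()` (unique reconstructions performed).
#' @export
make_recon_provider <- function(config = recon_config()) {
  cache <- new.env(parent = emptyenv())
  counts <- new.env(parent = emptyenv())
  fn <- function(case, context = "two_stage") {
    assign(context, (if (exists(context, counts)) get(context, counts)
                     else 0L) + 1L, counts)
    id <- case$case_id
    if (!exists(id, cache)) {
      ph <- case$phantom
      rec <- reconstruct_thb(case$measurements, ph$lesion_center,
                             ph$lesion_radius, ph$background, config)
      assign(id, thb_image(rec), cache)
    }
    get(id, cache)
  }
  list(fn = fn,
       counts = function() as.list(counts),
       n_computed = function() length(ls(cache)))
}

#' Pretrain the two DOT branches on a simulated cohort
#'
#' Trains the histogram branch on the cohort's histograms and, after
#' reconstructing every case, the image branch on the tHb maps. These
#' shared pretrained weights are the starting point for per-run
#' fine-tuning.
#'
#' @param pretrain_cohort A [build_cohort()] cohort (DOT-only is fine).
#' @param seed Integer seed.
#' @param recon_cfg [recon_config()] for the pretraining
#'   reconstructions.
#' @param verbose Print progress.
#' @return List with trained `hist` and `img` branches and the
#'   reconstructed `thb` array.
#' @export
pretrain_dot_branches <- function(pretrain_cohort, seed = 1,
                                  recon_cfg = recon_config(
                                    max_iterations = 40, tol = 1e-4),
                                  verbose = FALSE) {
  y <- cohort_labels(pretrain_cohort)
  xh <- histogram_input(lapply(pretrain_cohort, `[[`, "histogram"))
  hb <- train_hist_branch(hist_branch(seed), xh, y, seed = seed)
  n <- length(pretrain_cohort)
  thb <- array(0, c(32, 32, 3, n))
  for (i in seq_len(n)) {
    ph <- pretrain_cohort[[i]]$phantom
    rec <- reconstruct_thb(pretrain_cohort[[i]]$measurements,
                           ph$lesion_center, ph$lesion_radius,
                           ph$background, recon_cfg)
    thb[, , , i] <- thb_image(rec)
    if (verbose && i %% 100 == 0)
      message(sprintf("  pretraining reconstruction %d/%d", i, n))
  }
  ib <- train_img_branch(img_branch(seed), thb, y, seed = seed,
                         pretrain = TRUE)
  list(hist = hb, img = ib, thb = thb)
}

#' Cache US backbone features for a cohort
#'
#' Renders each case's surrogate ultrasound image, preprocesses it and
#' runs it through the frozen US backbone once.
#'
#' @param branch A [us_branch()].
#' @param cohort Cohort with ultrasound surrogates.
#' @param chunk Images per forward chunk.
#' @param verbose Print progress.
#' @return Array (7, 7, 512, n_cases).
#' @export
cache_us_features <- function(branch, cohort, chunk = 8, verbose = FALSE) {
  n <- length(cohort)
  out <- array(0, c(7, 7, 512, n))
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1)
    imgs <- array(0, c(224, 224, 3, e - s + 1))
    for (k in s:e)
      imgs[, , , k - s + 1] <- preprocess_us(case_us_image(cohort[[k]]))
    out[, , , s:e] <- us_backbone_features(branch, imgs, chunk = chunk)
    if (verbose && (e %% 64 == 0 || e == n))
      message(sprintf("  US backbone features %d/%d", e, n))
  }
  out
}

# out-of-fold stage-1 scores: stratified k-fold within the training
# set, so the threshold grid search sees honestly calibrated scores
# rather than near-zero training losses
stage1_oof_scores <- function(hist0, usb, xh, feats, y, k = 3, seed = 1) {
  n <- length(y)
  set.seed(seed)
  fold <- rep(NA_integer_, n)
  for (cl in unique(y)) {
    i <- which(y == cl)
    fold[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  p <- numeric(n)
  for (f in seq_len(k)) {
    tr <- which(fold != f); ho <- which(fold == f)
    hb <- train_hist_branch(hist0, xh[, , , tr, drop = FALSE], y[tr],
                            seed = seed + f)
    ub <- train_us_head(usb, feats[, , , tr, drop = FALSE], y[tr],
                        seed = seed + f)
    p[ho] <- (nn_predict(hb, xh[, , , ho, drop = FALSE]) +
                us_head_predict(ub, feats[, , , ho, drop = FALSE])) / 2
  }
  p
}

#' Bootstrap evaluation of the two-stage strategy
#'
#' For each of `n_runs` balanced train/test splits: fine-tune the
#' histogram branch and the US head on the training set, grid-search the
#' stage-1 threshold on out-of-fold training scores (stratified 3-fold
#' within the training set, so the threshold never sees overfit
#' in-sample scores nor any test data), reconstruct only the suspicious
#' training cases, fine-tune the image branch and train the fusion head
#' on them, then run the two-stage pipeline on the held-out test set.
#' Optionally also evaluates the single-stage baseline (all test cases
#' reconstructed) and per-branch AUCs. All randomness derives from
#' `seed`.
#'
#' @param cohort Fine-tuning cohort (with ultrasound surrogates).
#' @param pretrained Output of [pretrain_dot_branches()], or `NULL` to
#'   start the DOT branches from random initialisation.
#' @param n_runs Number of bootstrap runs.
#' @param seed Master seed.
#' @param n_train,n_test Per-class split sizes.
#' @param recon_cfg [recon_config()] used for case reconstructions.
#' @param us_seed Seed for the US branch weight initialisation.
#' @param include_single_stage,include_branch_auc Toggle the extra
#'   evaluation arms (each reconstructs all test cases).
#' @param verbose Print per-run progress.
#' @return Object of class `evaluation_report`: `per_run` data frame,
#'   `aggregate` (means and 2.5/97.5 percentile CIs), and the recon
#'   call-count audit.
#' @export
evaluate_bootstrap <- function(cohort, pretrained = NULL, n_runs = 50,
                               seed = 1, n_train = 60, n_test = 25,
                               recon_cfg = recon_config(
                                 max_iterations = 40, tol = 1e-4),
                               us_seed = NULL,
                               include_single_stage = TRUE,
                               include_branch_auc = TRUE,
                               verbose = FALSE) {
  set.seed(seed)
  sub <- sample.int(2^31 - 10, n_runs + 3)
  if (is.null(us_seed)) us_seed <- sub[n_runs + 1]
  usb <- us_branch(us_seed)
  if (verbose) message("caching US backbone features ...")
  us_feats <- cache_us_features(usb, cohort, verbose = verbose)
  splits <- make_bootstrap_splits(cohort, n_runs, seed = sub[n_runs + 2],
                                  n_train = n_train, n_test = n_test)
  ids <- cohort_ids(cohort)
  labels <- cohort_labels(cohort)
  provider <- make_recon_provider(recon_cfg)
  hist0 <- if (is.null(pretrained)) hist_branch(sub[n_runs + 3]) else
    pretrained$hist
  img0 <- if (is.null(pretrained)) img_branch(sub[n_runs + 3]) else
    pretrained$img
  xh_all <- histogram_input(lapply(cohort, `[[`, "histogram"))

  rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    rs <- sub[r]
    tr <- match(splits[[r]]$train_ids, ids)
    te <- match(splits[[r]]$test_ids, ids)
    ytr <- labels[tr]; yte <- labels[te]

    hb <- train_hist_branch(hist0, xh_all[, , , tr, drop = FALSE], ytr,
                            seed = rs)
    usb_r <- train_us_head(usb, us_feats[, , , tr, drop = FALSE], ytr,
                           seed = rs)
    p_oof <- stage1_oof_scores(hist0, usb, xh_all[, , , tr, drop = FALSE],
                               us_feats[, , , tr, drop = FALSE], ytr,
                               seed = rs)
    threshold <- grid_search_threshold(p_oof, ytr)

    # suspicious training group selected by the same out-of-fold scores
    susp_tr <- tr[p_oof >= threshold]
    thb_tr <- array(0, c(32, 32, 3, length(susp_tr)))
    for (k in seq_along(susp_tr))
      thb_tr[, , , k] <- provider$fn(cohort[[susp_tr[k]]], "train")
    y_susp <- labels[susp_tr]
    ib <- if (length(unique(y_susp)) >= 2L)
      train_img_branch(img0, thb_tr, y_susp, seed = rs, pretrain = FALSE)
    else img0
    fus <- fusion_head(rs)
    if (length(susp_tr)) {
      f_us <- us_head_features(usb_r,
        us_feats[, , , susp_tr, drop = FALSE])
      f_hist <- extract_features(hb,
        xh_all[, , , susp_tr, drop = FALSE])
      f_img <- extract_features(ib, thb_tr)
      fus <- train_fusion(fus, fuse_features(f_us, f_hist, f_img),
                          y_susp, seed = rs)
    } else fus$fallback <- TRUE

    models <- list(us = usb_r, hist = hb, img = ib, fusion = fus)
    res <- run_two_stage(cohort[te], models, threshold,
                         function(cs) provider$fn(cs, "two_stage"),
                         us_feats = us_feats[, , , te, drop = FALSE])
    cm <- combined_confusion(res)
    auc2 <- roc_auc(res$final_score, yte)$auc

    auc_us <- auc_hist <- auc_img <- NA_real_
    if (include_branch_auc) {
      auc_us <- roc_auc(res$p_us, yte)$auc
      auc_hist <- roc_auc(res$p_hist, yte)$auc
      thb_te <- array(0, c(32, 32, 3, length(te)))
      for (k in seq_along(te))
        thb_te[, , , k] <- provider$fn(cohort[[te[k]]], "branch_eval")
      auc_img <- roc_auc(nn_predict(ib, thb_te), yte)$auc
    }
    auc1 <- NA_real_
    if (include_single_stage) {
      # single-stage arm: image branch and fusion trained on the full
      # training set, evaluated on every test case
      thb_all_tr <- array(0, c(32, 32, 3, length(tr)))
      for (k in seq_along(tr))
        thb_all_tr[, , , k] <- provider$fn(cohort[[tr[k]]], "single_stage")
      ib1 <- train_img_branch(img0, thb_all_tr, ytr, seed = rs,
                              pretrain = FALSE)
      f_us <- us_head_features(usb_r, us_feats[, , , tr, drop = FALSE])
      f_hist <- extract_features(hb, xh_all[, , , tr, drop = FALSE])
      f_img <- extract_features(ib1, thb_all_tr)
      fus1 <- train_fusion(fusion_head(rs),
                           fuse_features(f_us, f_hist, f_img), ytr,
                           seed = rs)
      ss <- single_stage_baseline(cohort[te],
        list(us = usb_r, hist = hb, img = ib1, fusion = fus1),
        function(cs) provider$fn(cs, "single_stage"),
        us_feats = us_feats[, , , te, drop = FALSE])
      auc1 <- ss$auc
    }

    rows[[r]] <- data.frame(
      run = r, threshold = threshold,
      auc_two_stage = auc2, auc_single_stage = auc1,
      auc_us = auc_us, auc_hist = auc_hist, auc_img = auc_img,
      benign_filter_rate = cm$tb1 / sum(yte == "benign"),
      stage1_fn_rate = cm$fb1 / sum(yte == "malignant"),
      n_suspicious = sum(res$decision == "suspicious"),
      recon_calls_two_stage = attr(res, "n_recon_calls"),
      tm2 = cm$tm2, fm2 = cm$fm2, fb1 = cm$fb1, fb2 = cm$fb2,
      tb1 = cm$tb1, tb2 = cm$tb2)
    if (verbose)
      message(sprintf(paste0("run %02d: thr=%.2f AUC2=%.3f ",
                             "filt=%.2f fn=%.2f"),
                      r, threshold, auc2,
                      rows[[r]]$benign_filter_rate,
                      rows[[r]]$stage1_fn_rate))
  }
  per_run <- do.call(rbind, rows)
  metrics <- setdiff(names(per_run), "run")
  aggregate <- lapply(setNames(nm = metrics), function(m) {
    v <- per_run[[m]]
    if (all(is.na(v))) return(list(mean = NA, ci = c(NA, NA)))
    list(mean = mean(v), ci = unname(quantile(v, c(0.025, 0.975))))
  })
  structure(list(per_run = per_run, aggregate = aggregate,
                 recon_counts = provider$counts(),
                 n_unique_recons = provider$n_computed(),
                 seed = seed, n_runs = n_runs),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<evaluation_report> %d runs (seed %s)\n", x$n_runs,
              format(x$seed)))
  cat(sprintf("  two-stage AUC      %.3f [%.3f, %.3f]\n",
              a$auc_two_stage$mean, a$auc_two_stage$ci[1],
              a$auc_two_stage$ci[2]))
  if (!is.na(a$auc_single_stage$mean))
    cat(sprintf("  single-stage AUC   %.3f\n", a$auc_single_stage$mean))
  cat(sprintf("  benign filtered    %.1f%%\n",
              100 * a$benign_filter_rate$mean))
  cat(sprintf("  stage-1 FN rate    %.1f%%\n",
              100 * a$stage1_fn_rate$mean))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' `report.csv` holds the per-run metric rows; `report.json` the
#' aggregate means and percentile confidence intervals.
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$per_run, file.path(dir, "report.csv"),
            row.names = FALSE)
  jsonlite::write_json(report$aggregate, file.path(dir, "report.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
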