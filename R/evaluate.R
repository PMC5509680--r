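#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`, the standard spatial-overlap measure between
#' two binary segmentations. Two empty masks are defined to agree
#' perfectly (DSC 1); empty against non-empty gives 0.
#'
#' @param a,b binary 3D arrays, [label_map]s or [threshold_and_select()]
#'   `seg_mask`s of identical shape.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  a <- as_mask(a)
  b <- as_mask(b)
  if (!identical(dim(a), dim(b))) stopf("mask shapes differ")
  na <- sum(a)
  nb <- sum(b)
  if (na + nb == 0) return(1.0)
  2 * sum(a & b) / (na + nb)
}

as_mask <- function(x) {
  if (inherits(x, "seg_mask")) x <- x$mask
  if (inherits(x, "label_map")) x <- x$mask
  x != 0
}

#' Voxelwise ROC AUC of a probability map
#'
#' Area under the ROC curve treating every voxel's probability as a score
#' against the reference mask, computed tie-aware from midranks
#' (Mann-Whitney): a constant map scores exactly 0.5.
#'
#' @param p a [probability_map] or numeric array of scores.
#' @param truth a [label_map] or binary array of the same shape; must
#'   contain both classes.
#' @return AUC in `[0, 1]`.
#' @export
voxel_auc <- function(p, truth) {
  if (inherits(p, "probability_map")) p <- p$p
  truth <- as_mask(truth)
  if (!identical(dim(p), dim(truth))) stopf("map and truth shapes differ")
  pos <- as.vector(truth)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stopf("truth must contain both classes")
  r <- rank(as.vector(p))  # midranks: tie-aware
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Intraclass correlation for absolute agreement
#'
#' ICC(2,1): two-way random effects, absolute agreement, single rating,
#' computed from the two-way ANOVA mean squares, with the F-based 95%
#' confidence interval of McGraw & Wong and the F test of the subject
#' effect. Used here to quantify agreement of per-subject DSC values
#' across repeated trainings.
#'
#' @param ratings numeric matrix, subjects x raters/runs (>= 2 each, no
#'   missing cells).
#' @param conf confidence level (default 0.95).
#' @return List with `estimate`, `ci` (length 2), `p_value`, `n_subjects`,
#'   `n_raters`. If all ratings are identical the estimate is defined as 1
#'   with CI \[1, 1\].
#' @export
icc_agreement <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2 || k < 2) stopf("need >= 2 subjects and >= 2 raters")
  if (anyNA(ratings)) stopf("missing cells are not supported")
  if (max(ratings) - min(ratings) < .Machine$double.eps^0.5) {
    return(list(estimate = 1.0, ci = c(1.0, 1.0), p_value = NA_real_,
                n_subjects = n, n_raters = k))
  }
  gm <- mean(ratings)
  rm_ <- rowMeans(ratings)
  cm <- colMeans(ratings)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)                 # subjects
  msc <- n * sum((cm - gm)^2) / (k - 1)                  # raters
  sse <- sum((sweep(sweep(ratings, 1, rm_), 2, cm) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf
  if (mse <= 0) {
    ci <- c(est, est)
    p <- 0
  } else {
    fj <- msc / mse
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- (a * fj + b)^2 /
      ((a * fj)^2 / (k - 1) + b^2 / ((n - 1) * (k - 1)))
    f1 <- qf(1 - alpha / 2, n - 1, v)
    f2 <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f1 * mse) /
      (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f2 * msr)
    ci <- c(lower, upper)
    p <- pf(msr / mse, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  list(estimate = est, ci = ci, p_value = p, n_subjects = n, n_raters = k)
}

#' Per-subject segmentation metrics over a cohort
#'
#' @param maps list of [probability_map]s (held-out subjects).
#' @param masks list of `seg_mask`s (same order).
#' @param truths list of [label_map]s (same order).
#' @return Object of class `metrics_report`: a per-subject data frame
#'   (subject_id, dsc, auc) plus cohort mean/SD of each metric.
#' @export
metrics_report <- function(maps, masks, truths) {
  stopifnot(length(maps) == length(truths), length(masks) == length(truths))
  rows <- lapply(seq_along(maps), function(i) {
    data.frame(
      subject_id = maps[[i]]$subject_id %||% sprintf("subject-%d", i),
      dsc = dsc(masks[[i]], truths[[i]]),
      auc = voxel_auc(maps[[i]], truths[[i]]),
      stringsAsFactors = FALSE
    )
  })
  per_subject <- do.call(rbind, rows)
  structure(
    list(per_subject = per_subject,
         mean_dsc = mean(per_subject$dsc), sd_dsc = sd(per_subject$dsc),
         mean_auc = mean(per_subject$auc), sd_auc = sd(per_subject$auc),
         n_subjects = nrow(per_subject)),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d subjects: DSC %.3f (SD %.3f), AUC %.3f (SD %.3f)\n",
              x$n_subjects, x$mean_dsc, x$sd_dsc, x$mean_auc, x$sd_auc))
  invisible(x)
}

#' Stability of the pipeline across repeated trainings
#'
#' Repeats the entire sampling, splitting, training and prediction
#' procedure `n_runs` times with different seeds on a fixed phantom
#' cohort, collects the per-subject DSC of every run, and summarizes
#' agreement across runs with [icc_agreement()].
#'
#' @param cohort a `phantom_cohort`.
#' @param config an [experiment_config()]; its sampling/model/train/infer
#'   sections drive each run.
#' @param n_runs number of repeats (default 4).
#' @param seeds optional explicit per-run seeds (length `n_runs`);
#'   otherwise derived from `config$seed`.
#' @return Object of class `stability_report`: `dsc` (subjects x runs
#'   matrix), `icc`, `ci`, `p_value`, `n_runs`.
#' @export
stability_run <- function(cohort, config, n_runs = 4, seeds = NULL) {
  if (n_runs < 2) stopf("n_runs must be >= 2")
  if (is.null(seeds)) seeds <- derive_seeds(config$seed, n_runs)
  if (length(seeds) != n_runs) stopf("need one seed per run")
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- seeds[r]
    res <- tryCatch(
      run_experiment(cfg, cohort = cohort),
      error = function(e) stopf("stability run %d failed: %s", r,
                                conditionMessage(e))
    )
    runs[[r]] <- res$metrics$per_subject$dsc
  }
  mat <- do.call(cbind, runs)
  colnames(mat) <- paste0("run", seq_len(n_runs))
  icc <- icc_agreement(mat)
  structure(
    list(dsc = mat, icc = icc$estimate, ci = icc$ci, p_value = icc$p_value,
         n_runs = n_runs, seeds = seeds),
    class = "stability_report"
  )
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d runs x %d subjects: ICC %.3f (95%% CI %.3f-%.3f)\n",
              x$n_runs, nrow(x$dsc), x$icc, x$ci[1], x$ci[2]))
  invisible(x)
}
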