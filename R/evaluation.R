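#' Error metrics
#'
#' Mean absolute error, root mean square error, and the coefficient of
#' determination R^2 = 1 - SS_res / SS_tot about the reference mean. All in
#' the units of the inputs (mM here).
#'
#' @param pred,ref equal-length numeric vectors (length >= 2; >= 3 for R^2).
#' @return A single number.
#' @export
mae <- function(pred, ref) {
  .check_pair(pred, ref, 2L)
  mean(abs(pred - ref))
}

#' @rdname mae
#' @export
rmse <- function(pred, ref) {
  .check_pair(pred, ref, 2L)
  sqrt(mean((pred - ref)^2))
}

#' @rdname mae
#' @export
r2 <- function(pred, ref) {
  .check_pair(pred, ref, 3L)
  ss_tot <- sum((ref - mean(ref))^2)
  if (ss_tot == 0) stop("R^2 undefined: reference has zero variance")
  1 - sum((pred - ref)^2) / ss_tot
}

.check_pair <- function(pred, ref, n_min) {
  if (length(pred) != length(ref)) stop("pred and ref differ in length")
  if (length(ref) < n_min) stop(sprintf("need at least %d pairs", n_min))
  invisible(TRUE)
}

#' Relative deviation in percent
#'
#' (ref - pred) / ref * 100: a reference above the prediction gives a
#' positive deviation (the sign convention of the cohort comparison table).
#'
#' @param ref reference concentrations in mM, strictly positive.
#' @param pred predicted concentrations in mM.
#' @return Deviations in percent (vectorised).
#' @export
relative_deviation <- function(ref, pred) {
  if (any(ref <= 0)) stop("relative deviation requires positive references")
  (ref - pred) / ref * 100
}

#' Agreement rate within a deviation threshold
#'
#' Number and fraction of samples whose absolute relative deviation is at
#' most the threshold.
#'
#' @param ref,pred concentration vectors in mM.
#' @param threshold threshold in percent (e.g. 5 or 10).
#' @return A list with `count` and `fraction`.
#' @export
agreement_within <- function(ref, pred, threshold) {
  .check_pair(pred, ref, 1L)
  ok <- abs(relative_deviation(ref, pred)) <= threshold
  list(count = sum(ok), fraction = mean(ok))
}

#' Bland-Altman agreement analysis
#'
#' Differences are oriented pred - ref; the bias is their mean and the 95%
#' limits of agreement are bias +/- 1.96 times the sample SD (n-1
#' denominator).
#'
#' @param pred,ref concentration vectors in mM, n >= 3.
#' @return A list with `bias`, `loa_low`, `loa_high` (mM).
#' @export
bland_altman <- function(pred, ref) {
  .check_pair(pred, ref, 3L)
  d <- pred - ref
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' Bootstrap percentile confidence interval for a paired statistic
#'
#' Seeded paired resampling: each replicate draws n indices with
#' replacement and recomputes `statistic(pred[i], ref[i])`; the central 95%
#' percentile interval is returned.
#'
#' @param statistic function of `(pred, ref)` returning one number, e.g.
#'   [rmse()] or the Bland-Altman bias.
#' @param pred,ref concentration vectors in mM.
#' @param reps number of bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @param level confidence level.
#' @return A list with `lo` and `hi`.
#' @export
bootstrap_ci <- function(statistic, pred, ref, reps = 2000, seed = 42L,
                         level = 0.95) {
  .check_pair(pred, ref, 2L)
  if (reps < 100) stop("use at least 100 bootstrap replicates")
  set.seed(seed)
  n <- length(ref)
  stats <- vapply(seq_len(reps), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    statistic(pred[i], ref[i])
  }, numeric(1))
  alpha <- (1 - level) / 2
  q <- unname(stats::quantile(stats, c(alpha, 1 - alpha), type = 7))
  list(lo = q[1], hi = q[2])
}

#' Paired significance tests for systematic bias
#'
#' Two-sided paired t-test and Wilcoxon signed-rank test on the differences
#' pred - ref. With all-zero differences both tests are degenerate; the
#' p-values are reported as 1 with `degenerate = TRUE`.
#'
#' @param pred,ref concentration vectors in mM, n >= 6.
#' @return A list with `p_ttest`, `p_wilcoxon`, `degenerate`.
#' @export
paired_tests <- function(pred, ref) {
  .check_pair(pred, ref, 6L)
  d <- pred - ref
  if (all(d == 0) || stats::sd(d) == 0) {
    return(list(p_ttest = 1, p_wilcoxon = 1, degenerate = TRUE))
  }
  list(p_ttest = stats::t.test(pred, ref, paired = TRUE)$p.value,
       p_wilcoxon = suppressWarnings(
         stats::wilcox.test(pred, ref, paired = TRUE, exact = FALSE)$p.value),
       degenerate = FALSE)
}

#' Full method-agreement report
#'
#' Computes the complete agreement suite for one analyte: MAE, RMSE, R^2,
#' agreement rates at the requested thresholds, Bland-Altman bias and
#' limits, bootstrap CIs for RMSE and bias, and paired tests.
#'
#' @param pred,ref concentration vectors in mM.
#' @param thresholds agreement thresholds in percent.
#' @param reps,seed bootstrap settings (see [bootstrap_ci()]).
#' @return An object of class `eval_report`.
#' @export
eval_report <- function(pred, ref, thresholds = c(5, 10), reps = 2000,
                        seed = 42L) {
  ba <- bland_altman(pred, ref)
  agreement <- lapply(thresholds, function(th) agreement_within(ref, pred, th))
  names(agreement) <- paste0("within_", thresholds, "pct")
  structure(list(
    n = length(ref),
    mae = mae(pred, ref), rmse = rmse(pred, ref), r2 = r2(pred, ref),
    agreement_rates = agreement,
    bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
    ci_rmse = bootstrap_ci(rmse, pred, ref, reps, seed),
    ci_bias = bootstrap_ci(function(p, r) mean(p - r), pred, ref, reps,
                           seed + 1L),
    p_ttest = paired_tests(pred, ref)$p_ttest,
    p_wilcoxon = paired_tests(pred, ref)$p_wilcoxon
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d  MAE %.4g  RMSE %.4g  R2 %.4f\n",
              x$n, x$mae, x$rmse, x$r2))
  for (nm in names(x$agreement_rates)) {
    a <- x$agreement_rates[[nm]]
    cat(sprintf("  %s: %d/%d (%.1f%%)\n", nm, a$count, x$n, 100 * a$fraction))
  }
  cat(sprintf("  bias %.4g mM, LoA [%.4g, %.4g]; p(t)=%.3g, p(Wilcoxon)=%.3g\n",
              x$bias, x$loa_low, x$loa_high, x$p_ttest, x$p_wilcoxon))
  invisible(x)
}

#' Five-fold cross-validation with leakage-free scaling
#'
#' Seeded shuffled partition into `k` near-equal folds; each fold serves
#' once as validation while the trainer (which must fit any scaler on its
#' training rows only, as the packaged model constructors do) is refitted
#' on the remainder.
#'
#' @param data data frame of cases.
#' @param k number of folds.
#' @param trainer function(train_df) returning a model with a `predict`
#'   method.
#' @param targets target column name(s) used to score the fold.
#' @param seed integer seed for the partition.
#' @return A list with `folds` (per-fold data frames of mae/rmse per
#'   target), `assignments` (fold id per row), and `aggregate` (mean of the
#'   per-fold metrics).
#' @export
kfold_cv <- function(data, k = 5, trainer, targets, seed = 1L) {
  n <- nrow(data)
  if (k > n) stop("k exceeds the number of rows")
  set.seed(seed)
  assignments <- sample(rep(seq_len(k), length.out = n))
  folds <- lapply(seq_len(k), function(f) {
    tr <- data[assignments != f, , drop = FALSE]
    va <- data[assignments == f, , drop = FALSE]
    model <- trainer(tr)
    pred <- predict(model, va)
    pred <- matrix(pred, nrow = nrow(va),
                   dimnames = list(NULL, targets))
    do.call(rbind, lapply(targets, function(tg) {
      data.frame(fold = f, target = tg,
                 mae = mae(pred[, tg], va[[tg]]),
                 rmse = rmse(pred[, tg], va[[tg]]))
    }))
  })
  folds <- do.call(rbind, folds)
  aggregate <- stats::aggregate(cbind(mae, rmse) ~ target, folds, mean)
  list(folds = folds, assignments = assignments, aggregate = aggregate)
}

#' Pairwise Pearson correlation matrix
#'
#' Symmetric matrix with unit diagonal; zero-variance columns are flagged
#' with a warning and returned as NA rows/columns.
#'
#' @param features numeric matrix or data frame (>= 3 rows).
#' @return Correlation matrix.
#' @export
pearson_matrix <- function(features) {
  x <- as.matrix(features)
  if (nrow(x) < 3L) stop("need at least 3 rows")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("zero-variance feature(s): %s",
                    paste(colnames(x)[sds == 0], collapse = ", ")))
  }
  suppressWarnings(stats::cor(x))
}
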