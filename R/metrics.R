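#' Regression accuracy metrics
#'
#' Root mean square error, Pearson correlation, coefficient of
#' determination, and the min / median / max of the signed errors
#' `pred - ref` (the three summaries of the folded empirical cumulative
#' distribution of errors).
#'
#' @param pred numeric vector of predictions.
#' @param ref numeric vector of reference values (same length, >= 2, not
#'   constant).
#' @return An object of class `metrics_report`: `rmse`, `r`, `r_squared`,
#'   `ecdp_min`, `ecdp_median`, `ecdp_max`, `n`.
#' @export
regression_metrics <- function(pred, ref) {
  pred <- as.numeric(pred)
  ref <- as.numeric(ref)
  if (length(pred) != length(ref)) stop("pred and ref lengths differ")
  n <- length(pred)
  if (n < 2L) stop("at least 2 paired values are required")
  if (stats::sd(ref) <= 0) {
    stop("reference values are constant: correlation undefined")
  }
  e <- pred - ref
  rmse <- sqrt(mean(e^2))
  r <- stats::cor(pred, ref)
  ss_res <- sum(e^2)
  ss_tot <- sum((ref - mean(ref))^2)
  structure(
    list(rmse = rmse, r = r, r_squared = 1 - ss_res / ss_tot,
         ecdp_min = min(e), ecdp_median = stats::median(e),
         ecdp_max = max(e), n = n),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("n = %d  RMSE = %.4f  R = %.4f  R^2 = %.4f\n", x$n, x$rmse,
              x$r, x$r_squared))
  cat(sprintf("signed errors: min %.4f, median %.4f, max %.4f\n",
              x$ecdp_min, x$ecdp_median, x$ecdp_max))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Assesses agreement between a predictive method and the reference via
#' the paired differences `d = pred - ref` (in target units, kg for dry
#' weight): their mean and sample standard deviation, the 95% confidence
#' interval of the mean (\eqn{\pm 1.96\,sd/\sqrt{N}}), the limits of
#' agreement (\eqn{mean \pm 1.96\,sd}), and the number of points strictly
#' outside the limits. The clinical acceptability rule requires that
#' fewer than 5% of points (count threshold `ceiling(0.05 N)`) fall
#' outside the limits; for a 476-patient cohort the threshold is 24.
#'
#' @param pred numeric vector of predictions.
#' @param ref numeric vector of reference measurements (length >= 3).
#' @return An object of class `agreement_report`: `mean_diff`, `sd_diff`,
#'   `ci_low`, `ci_high`, `loa_low`, `loa_high`, `n_outside`,
#'   `ratio_outside`, `threshold`, `acceptable`, `n`.
#' @export
bland_altman <- function(pred, ref) {
  pred <- as.numeric(pred)
  ref <- as.numeric(ref)
  if (length(pred) != length(ref)) stop("pred and ref lengths differ")
  n <- length(pred)
  if (n < 3L) stop("Bland-Altman analysis needs at least 3 pairs")
  d <- pred - ref
  m <- mean(d)
  s <- stats::sd(d)
  loa_low <- m - 1.96 * s
  loa_high <- m + 1.96 * s
  n_outside <- sum(d < loa_low | d > loa_high)
  threshold <- ceiling(0.05 * n)
  structure(
    list(mean_diff = m, sd_diff = s,
         ci_low = m - 1.96 * s / sqrt(n), ci_high = m + 1.96 * s / sqrt(n),
         loa_low = loa_low, loa_high = loa_high,
         n_outside = n_outside, ratio_outside = n_outside / n,
         threshold = threshold, acceptable = n_outside < threshold, n = n),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("mean difference %.4f (95%% CI %.4f to %.4f), sd %.4f\n",
              x$mean_diff, x$ci_low, x$ci_high, x$sd_diff))
  cat(sprintf("limits of agreement %.4f to %.4f\n", x$loa_low, x$loa_high))
  cat(sprintf("outside limits: %d/%d (%.2f%%), threshold %d -> %s\n",
              x$n_outside, x$n, 100 * x$ratio_outside, x$threshold,
              if (x$acceptable) "acceptable" else "not acceptable"))
  invisible(x)
}

# Deterministic partition of N shuffled rows into k folds of size
# differing by at most one (the first N %% k folds get the extra row).
kfold_assign <- function(n, k, seed) {
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  perm <- with_local_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), times = sizes)
  fold
}

#' k-fold cross-validation of the RBF models
#'
#' Shuffles the cohort with the given seed, partitions it into `k` folds
#' of size differing by at most one, and for each fold: standardizes on
#' the training rows only, fits the requested model, and predicts the
#' held-out rows (the test rows are transformed with the training-fold
#' scaler and never enter the Laplacians). Held-out predictions are pooled
#' in the original row order and the metric and agreement reports are
#' computed once on the pooled vector.
#'
#' @param cohort a raw [cohort_table()].
#' @param k number of folds (default 10).
#' @param seed integer seed for the shuffle (also offsets the per-fold
#'   center-selection seeds deterministically).
#' @param model `"mlaprbfn"` (default) or `"rbfn"`.
#' @param control an [mlap_control()]; for `model = "rbfn"` only `p` and
#'   `seed` are used.
#' @return An object of class `cv_result`: pooled `predictions` (N x q),
#'   `fold` assignments, `metrics` ([regression_metrics()]),
#'   `agreement` ([bland_altman()]), and the call parameters.
#' @export
kfold_cv <- function(cohort, k = 10L, seed = 1L, model = c("mlaprbfn", "rbfn"),
                     control = mlap_control()) {
  stopifnot(inherits(cohort, "cohort_table"))
  model <- match.arg(model)
  n <- nrow(cohort$X)
  if (k < 2L || k > n) stop("k must satisfy 2 <= k <= N")
  fold <- kfold_assign(n, k, seed)
  min_train <- n - max(tabulate(fold, k))
  if (control$p > min_train) {
    stop("p = ", control$p, " exceeds the smallest training-fold size (",
         min_train, ")")
  }
  preds <- matrix(NA_real_, n, ncol(cohort$Y))
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    train <- cohort_subset(cohort, which(fold != f))
    fold_seed <- seed + f
    if (model == "rbfn") {
      fit <- rbfn(train, p = control$p, seed = fold_seed)
    } else {
      ctl <- control
      ctl$seed <- fold_seed
      fit <- mlaprbfn(train, ctl)
    }
    preds[test_idx, ] <- stats::predict(fit,
                                        cohort$X[test_idx, , drop = FALSE])
  }
  structure(
    list(predictions = preds, fold = fold,
         metrics = regression_metrics(preds[, 1L], cohort$Y[, 1L]),
         agreement = bland_altman(preds[, 1L], cohort$Y[, 1L]),
         model = model, k = k, seed = seed, control = control),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV of %s (seed %d):\n", x$k, x$model, x$seed))
  print(x$metrics)
  print(x$agreement)
  invisible(x)
}
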