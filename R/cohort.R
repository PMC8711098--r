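#' Construct a cohort table
#'
#' A `cohort_table` bundles the predictor matrix `X` (one row per patient),
#' the continuous target matrix `Y` (dry weight in kg for the clinical
#' schema), the column labels, and -- once [standardize_cohort()] has been
#' applied -- the per-column standardization parameters, so that the exact
#' training-fold transform can be replayed on held-out rows.
#'
#' Categorical predictors must be numerically encoded before construction;
#' for the clinical schema, gender is coded male = 1, female = 0.
#'
#' @param X numeric matrix or data frame, N x d predictors.
#' @param Y numeric matrix or vector, N x q targets (q = 1 for dry weight).
#' @param column_names optional predictor labels (defaults to `colnames(X)`).
#' @param target_names optional target labels.
#' @param scaler optional list of per-column `(mean, sd)` pairs as produced
#'   by [standardize_cohort()]; `NULL` for raw data.
#' @return An object of class `cohort_table` with elements `X`, `Y`,
#'   `column_names`, `target_names`, `scaler`.
#' @seealso [standardize_cohort()], [read_cohort_csv()], [generate_cohort()]
#' @export
cohort_table <- function(X, Y, column_names = NULL, target_names = NULL,
                         scaler = NULL) {
  X <- as.matrix(X)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1L)
  Y <- as.matrix(Y)
  storage.mode(X) <- "double"
  storage.mode(Y) <- "double"
  if (nrow(X) < 1L) stop("cohort must contain at least one row")
  if (nrow(X) != nrow(Y)) {
    stop("X and Y must have the same number of rows (", nrow(X), " vs ",
         nrow(Y), ")")
  }
  if (is.null(column_names)) {
    column_names <- colnames(X)
    if (is.null(column_names)) column_names <- paste0("x", seq_len(ncol(X)))
  }
  if (is.null(target_names)) {
    target_names <- colnames(Y)
    if (is.null(target_names)) target_names <- paste0("y", seq_len(ncol(Y)))
  }
  colnames(X) <- column_names
  colnames(Y) <- target_names
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("missing or non-finite predictor value at row ", bad[1L, 1L],
         ", column '", column_names[bad[1L, 2L]], "'")
  }
  bad_y <- which(!is.finite(Y), arr.ind = TRUE)
  if (nrow(bad_y) > 0L) {
    stop("missing or non-finite target value at row ", bad_y[1L, 1L])
  }
  structure(
    list(X = X, Y = Y, column_names = column_names,
         target_names = target_names, scaler = scaler),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort table:", nrow(x$X), "patients,", ncol(x$X), "predictors (",
      paste(x$column_names, collapse = ", "), "),", ncol(x$Y), "target(s)\n")
  cat(if (is.null(x$scaler)) "raw (not standardized)\n" else
    "standardized (scaler attached)\n")
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$X)

#' Standardize cohort predictors
#'
#' Z-scores every predictor column (sample standard deviation, n - 1
#' denominator) and records the per-column `(mean, sd)` so the identical
#' transform can be applied to new rows with [apply_scaler()]. Targets are
#' left untouched. Standardization matters here because center selection
#' and all four similarity kernels are scale-sensitive while the clinical
#' predictors span incomparable units (mmHg, years, beats/min).
#'
#' @param cohort a [cohort_table()].
#' @return The cohort with standardized `X` and the scaler recorded.
#' @export
standardize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  X <- cohort$X
  mu <- colMeans(X)
  sd_ <- apply(X, 2L, stats::sd)
  zero <- which(sd_ <= 0 | !is.finite(sd_))
  if (length(zero) > 0L) {
    stop("constant predictor column '", cohort$column_names[zero[1L]],
         "': cannot standardize a zero-variance column")
  }
  Xs <- sweep(sweep(X, 2L, mu, "-"), 2L, sd_, "/")
  scaler <- list(mean = mu, sd = sd_)
  cohort_table(Xs, cohort$Y, cohort$column_names, cohort$target_names,
               scaler = scaler)
}

#' Apply a recorded standardization to new rows
#'
#' @param X numeric matrix of raw predictors (same columns as the training
#'   cohort).
#' @param scaler the `scaler` element of a standardized [cohort_table()].
#' @return The transformed matrix.
#' @export
apply_scaler <- function(X, scaler) {
  X <- as.matrix(X)
  if (ncol(X) != length(scaler$mean)) {
    stop("predictor dimension mismatch: got ", ncol(X), " columns, scaler ",
         "has ", length(scaler$mean))
  }
  sweep(sweep(X, 2L, scaler$mean, "-"), 2L, scaler$sd, "/")
}

#' Read a cohort from CSV
#'
#' Expects a header row; the column named by `target` becomes `Y`, all
#' remaining numeric columns become predictors in file order.
#'
#' @param path CSV file path.
#' @param target name of the target column (default `"dry_weight"`).
#' @return A [cohort_table()].
#' @export
read_cohort_csv <- function(path, target = "dry_weight") {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!target %in% names(df)) {
    stop("target column '", target, "' not found in ", path)
  }
  Y <- as.matrix(df[[target]])
  colnames(Y) <- target
  Xdf <- df[setdiff(names(df), target)]
  cohort_table(as.matrix(Xdf), Y)
}

#' Write a cohort to CSV
#'
#' @param cohort a [cohort_table()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  df <- data.frame(cohort$X, check.names = FALSE)
  for (j in seq_len(ncol(cohort$Y))) df[[cohort$target_names[j]]] <- cohort$Y[, j]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Subset the rows of a cohort
#'
#' @param cohort a [cohort_table()].
#' @param idx integer row indices.
#' @return A [cohort_table()] with the selected rows (scaler dropped:
#'   standardization statistics are fold-specific).
#' @export
cohort_subset <- function(cohort, idx) {
  stopifnot(inherits(cohort, "cohort_table"))
  cohort_table(cohort$X[idx, , drop = FALSE], cohort$Y[idx, , drop = FALSE],
               cohort$column_names, cohort$target_names)
}

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
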