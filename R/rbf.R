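#' Select RBF centers by k-means
#'
#' Runs k-means on the (standardized) predictor rows to place the `p`
#' hidden-node centers. Initialization is k-means++ with `nstart` restarts;
#' the restart with the lowest total within-cluster sum of squares wins.
#' Deterministic for a fixed `(X, p, seed)`.
#'
#' @param X numeric matrix N x d of standardized predictors.
#' @param p number of centers (clusters); `2 <= p <= N`.
#' @param seed integer RNG seed for initialization.
#' @param nstart number of k-means++ restarts (default 10).
#' @param iter_max Lloyd iteration cap per restart.
#' @return A `p x d` matrix of cluster centroids.
#' @export
select_centers <- function(X, p, seed, nstart = 10L, iter_max = 100L) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (p > N) stop("p = ", p, " centers requested but only N = ", N, " rows")
  if (p < 2L) stop("p must be at least 2 (the width rule needs >= 2 centers)")
  if (p == N) return(unname(X))
  with_local_seed(seed, {
    best <- NULL
    for (r in seq_len(nstart)) {
      init <- kmeanspp_init(X, p)
      km <- tryCatch(
        stats::kmeans(X, centers = init, iter.max = iter_max,
                      algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) {
          # Lloyd warns on non-convergence / empty clusters; keep the fit
          suppressWarnings(stats::kmeans(X, centers = init,
                                         iter.max = iter_max,
                                         algorithm = "Lloyd"))
        })
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best)) stop("k-means failed for every restart; is p too ",
                            "large for the number of distinct rows?")
    unname(best$centers)
  })
}

# k-means++ seeding: first center uniform, then each subsequent center drawn
# with probability proportional to squared distance to the nearest chosen one.
kmeanspp_init <- function(X, p) {
  N <- nrow(X)
  centers <- matrix(NA_real_, p, ncol(X))
  idx <- sample.int(N, 1L)
  centers[1L, ] <- X[idx, ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ], "-")^2)
  for (j in seq_len(p - 1L) + 1L) {
    if (sum(d2) <= 0) {
      # all remaining points coincide with a chosen center
      idx <- sample.int(N, 1L)
    } else {
      idx <- sample.int(N, 1L, prob = d2)
    }
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ], "-")^2))
  }
  centers
}

#' Shared RBF width from the selected centers
#'
#' The Gaussian basis functions share a single width
#' \eqn{\sigma = \sigma_{max} / \sqrt{2p}}, where \eqn{\sigma_{max}} is the
#' maximum pairwise Euclidean distance among the `p` centers.
#'
#' @param centers numeric matrix p x d of center vectors.
#' @return The positive scalar width.
#' @export
rbf_width <- function(centers) {
  centers <- as.matrix(centers)
  p <- nrow(centers)
  if (p < 2L) stop("the width rule needs at least 2 centers")
  sigma_max <- max(stats::dist(centers))
  if (sigma_max <= 0) {
    stop("all centers coincide (max pairwise distance is 0): degenerate basis")
  }
  sigma_max / sqrt(2 * p)
}

#' Construct an RBF basis
#'
#' Convenience constructor running [select_centers()] then [rbf_width()].
#'
#' @inheritParams select_centers
#' @return An object of class `rbf_basis` with elements `centers`, `sigma`,
#'   `p`.
#' @export
rbf_basis <- function(X, p, seed, nstart = 10L) {
  centers <- select_centers(X, p, seed, nstart = nstart)
  structure(list(centers = centers, sigma = rbf_width(centers), p = p),
            class = "rbf_basis")
}

#' @export
print.rbf_basis <- function(x, ...) {
  cat("RBF basis:", x$p, "centers in", ncol(x$centers),
      "dimensions, shared width sigma =", format(x$sigma), "\n")
  invisible(x)
}

#' RBF design matrix
#'
#' Evaluates every Gaussian basis function at every row of `X`:
#' \eqn{\Phi_{ij} = \exp(-\|x_i - c_j\|^2 / (2\sigma^2))}. Entries lie in
#' (0, 1], with 1 exactly when a row coincides with a center.
#'
#' @param X numeric matrix N x d.
#' @param basis an [rbf_basis()] (or any list with `centers` and `sigma`).
#' @return The N x p design matrix.
#' @export
rbf_design <- function(X, basis) {
  X <- as.matrix(X)
  centers <- as.matrix(basis$centers)
  sigma <- basis$sigma
  if (is.null(sigma) || sigma <= 0) stop("basis width sigma must be positive")
  if (ncol(X) != ncol(centers)) {
    stop("predictor dimension mismatch: data has ", ncol(X),
         " columns, centers have ", ncol(centers))
  }
  d2 <- outer(rowSums(X^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(X)), rowSums(centers^2)) -
    2 * tcrossprod(X, centers)
  d2[d2 < 0] <- 0  # guard tiny negative round-off
  exp(-d2 / (2 * sigma^2))
}

#' Closed-form RBF network output weights
#'
#' Solves the unregularized least-squares readout
#' \eqn{W^* = (\Phi^T\Phi)^{-1}\Phi^T Y} through the normal equations with a
#' symmetric (Cholesky) solve; no ridge term is added, so a rank-deficient
#' design is an error rather than a silently shrunken fit.
#'
#' @param Phi N x p design matrix from [rbf_design()].
#' @param Y N x q target matrix.
#' @return The p x q weight matrix.
#' @export
rbfn_weights <- function(Phi, Y) {
  Phi <- as.matrix(Phi)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1L)
  if (nrow(Phi) != nrow(Y)) stop("Phi and Y must have the same number of rows")
  A <- crossprod(Phi)
  b <- crossprod(Phi, Y)
  R <- if (rcond(A) > 1e-12) tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    stop("the Gram matrix Phi'Phi is rank-deficient; reduce the number of ",
         "centers p, or use the Laplacian-regularized solver which is ",
         "well-posed under collinearity")
  }
  W <- backsolve(R, forwardsolve(t(R), b))
  dimnames(W) <- NULL
  W
}

#' Predict from an RBF basis and weight matrix
#'
#' Builds the design matrix of the new rows against the trained basis and
#' applies the linear readout. New rows must already be on the training
#' scale (apply the training-fold scaler first).
#'
#' @param X_new numeric matrix M x d of standardized predictors.
#' @param basis the trained [rbf_basis()].
#' @param W the p x q weight matrix.
#' @return The M x q matrix of predictions.
#' @export
rbf_predict <- function(X_new, basis, W) {
  W <- as.matrix(W)
  Phi_new <- rbf_design(X_new, basis)
  Phi_new %*% W
}

#' Fit a plain RBF network
#'
#' The two-stage baseline: standardize the cohort, place `p` centers by
#' k-means, set the shared width from the maximum center distance, and
#' solve the linear readout in closed form. This is the unregularized
#' reference model that [mlaprbfn()] reduces to when both penalties are 0.
#'
#' @param cohort a raw (unstandardized) [cohort_table()].
#' @param p number of hidden nodes (default 140).
#' @param seed integer seed for center selection.
#' @param nstart k-means restarts.
#' @return An object of class `rbfn` with the basis, weights and scaler.
#' @export
rbfn <- function(cohort, p = 140L, seed = 1L, nstart = 10L) {
  stopifnot(inherits(cohort, "cohort_table"))
  std <- standardize_cohort(cohort)
  basis <- rbf_basis(std$X, p, seed, nstart = nstart)
  Phi <- rbf_design(std$X, basis)
  W <- rbfn_weights(Phi, std$Y)
  structure(
    list(basis = basis, W = W, scaler = std$scaler,
         column_names = cohort$column_names,
         target_names = cohort$target_names,
         fitted = Phi %*% W, p = p, seed = seed),
    class = "rbfn"
  )
}

#' @export
print.rbfn <- function(x, ...) {
  cat("RBF network:", x$basis$p, "hidden nodes, sigma =",
      format(x$basis$sigma), "\n")
  invisible(x)
}

#' Predict method for plain RBF networks
#'
#' @param object an [rbfn()] fit.
#' @param newdata raw predictor matrix (training-scale standardization is
#'   applied internally using the stored scaler).
#' @param ... unused.
#' @return Matrix of predictions, one row per row of `newdata`.
#' @export
predict.rbfn <- function(object, newdata, ...) {
  Xs <- apply_scaler(newdata, object$scaler)
  rbf_predict(Xs, object$basis, object$W)
}
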