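#' Solver hyperparameters
#'
#' Collects the tunables of the multi-view Laplacian-regularized RBF
#' network. Defaults are the selected operating point of the method:
#' 140 hidden nodes, 10 alternating iterations, both penalty weights at
#' \eqn{2^{-3}}, kernel constant \eqn{\gamma = 1}, all four graph views,
#' and weight exponent \eqn{\rho = 2} (the simplest admissible value,
#' making each view weight inversely proportional to its smoothness trace).
#'
#' @param p hidden nodes / k-means clusters (>= 2).
#' @param tmax alternating iterations (>= 1).
#' @param lambda1 Laplacian penalty weight (>= 0).
#' @param lambda2 L2,1 row-sparsity penalty weight (>= 0).
#' @param rho exponent on the view weights (> 1).
#' @param gamma kernel constant.
#' @param kernels integer subset of 1:4 selecting the graph views.
#' @param eps_irls floor on row norms in the IRLS diagonal (guards the
#'   1/norm division for zeroed rows).
#' @param eps_trace floor on smoothness traces in the view-weight update
#'   (indefinite Laplacians from kernels 2-4 can give non-positive traces,
#'   which would break the negative-power update).
#' @param seed integer seed for center selection.
#' @param early_stop if `TRUE`, stop when the relative objective change
#'   drops below `tol`; off by default (the fixed `tmax` schedule is the
#'   method's stated protocol).
#' @param tol relative-change tolerance for `early_stop`.
#' @return An object of class `mlap_control`.
#' @export
mlap_control <- function(p = 140L, tmax = 10L, lambda1 = 2^-3,
                         lambda2 = 2^-3, rho = 2, gamma = 1, kernels = 1:4,
                         eps_irls = 1e-8, eps_trace = 1e-12, seed = 1L,
                         early_stop = FALSE, tol = 1e-6) {
  if (p < 2L) stop("p must be at least 2")
  if (tmax < 1L) stop("tmax must be at least 1")
  if (lambda1 < 0 || lambda2 < 0) stop("penalty weights must be non-negative")
  if (rho <= 1) stop("rho must exceed 1")
  structure(list(p = as.integer(p), tmax = as.integer(tmax),
                 lambda1 = lambda1, lambda2 = lambda2, rho = rho,
                 gamma = gamma, kernels = as.integer(kernels),
                 eps_irls = eps_irls, eps_trace = eps_trace,
                 seed = as.integer(seed), early_stop = early_stop,
                 tol = tol),
            class = "mlap_control")
}

#' Regularized objective value
#'
#' \deqn{J = \tfrac12\|\Phi W - Y\|_F^2
#'   + \tfrac{\lambda_1}{2}\,\mathrm{Tr}\big((\Phi W)^T
#'     \textstyle\sum_v \eta_v^{\rho} L_v (\Phi W)\big)
#'   + \tfrac{\lambda_2}{2}\sum_j \|W_{j\cdot}\|_2}
#'
#' The sparsity term is the (non-squared) L2,1 norm of the readout matrix:
#' the IRLS diagonal used by the solver is exactly the reweighting of this
#' form, so this is the quantity the alternating updates drive downhill.
#'
#' @param Phi N x p design matrix.
#' @param Y N x q targets.
#' @param W p x q readout weights.
#' @param L_list list of V Laplacians.
#' @param eta view weights on the simplex.
#' @param lambda1,lambda2 penalty weights.
#' @param rho view-weight exponent.
#' @return The scalar objective value.
#' @export
mlap_objective <- function(Phi, Y, W, L_list, eta, lambda1, lambda2,
                           rho = 2) {
  FW <- Phi %*% W
  R <- FW - Y
  fit <- 0.5 * sum(R^2)
  lap <- 0
  for (v in seq_along(L_list)) {
    lap <- lap + eta[v]^rho * sum(FW * (L_list[[v]] %*% FW))
  }
  l21 <- sum(sqrt(rowSums(W^2)))
  fit + 0.5 * lambda1 * lap + 0.5 * lambda2 * l21
}

#' IRLS diagonal for the L2,1 penalty
#'
#' \eqn{G_{jj} = 1 / (2\,\max(\|W_{j\cdot}\|_2,\ \epsilon))}. The floor
#' keeps the reweighting finite when a row has been driven to zero.
#'
#' @param W p x q weight matrix.
#' @param eps_irls row-norm floor.
#' @return Numeric vector of the p diagonal entries.
#' @export
update_irls <- function(W, eps_irls = 1e-8) {
  W <- as.matrix(W)
  1 / (2 * pmax(sqrt(rowSums(W^2)), eps_irls))
}

#' Closed-form readout update
#'
#' Solves \eqn{(\Phi^T\Phi + \lambda_1 \Phi^T L^* \Phi + \lambda_2 G)\,W =
#' \Phi^T Y} for the readout weights, the stationarity condition of the
#' quadratic surrogate at the current IRLS diagonal and fused Laplacian.
#' If the system matrix is numerically singular the solve is retried once
#' with a 1e-10 ridge jitter (with a warning); failure after that is an
#' error.
#'
#' @param Phi N x p design matrix.
#' @param Y N x q targets.
#' @param L_star fused N x N Laplacian from [fuse_laplacians()].
#' @param g the IRLS diagonal as a length-p vector from [update_irls()].
#' @param lambda1,lambda2 penalty weights.
#' @return The p x q weight matrix.
#' @export
update_weights <- function(Phi, Y, L_star, g, lambda1, lambda2) {
  Phi <- as.matrix(Phi)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1L)
  A <- crossprod(Phi) + lambda1 * crossprod(Phi, L_star %*% Phi)
  diag(A) <- diag(A) + lambda2 * g
  A <- (A + t(A)) / 2
  b <- crossprod(Phi, Y)
  W <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(W)) {
    warning("singular system in the readout update; retrying with 1e-10 ",
            "ridge jitter")
    diag(A) <- diag(A) + 1e-10
    W <- tryCatch(solve(A, b), error = function(e) {
      stop("readout update failed: system matrix singular even after jitter")
    })
  }
  dimnames(W) <- NULL
  W
}

#' Simplex-constrained view-weight update
#'
#' For fixed readout weights, the optimal simplex weights minimize
#' \eqn{\sum_v \eta_v^{\rho} h_v} with
#' \eqn{h_v = \mathrm{Tr}((\Phi W)^T L_v (\Phi W))}, giving the closed form
#' \eqn{\eta_v \propto h_v^{-1/(\rho-1)}}. Traces are floored at
#' `eps_trace` before the negative power; if every trace sits at the floor
#' the update degenerates to uniform weights (with a warning).
#'
#' @param Phi N x p design matrix.
#' @param W p x q readout weights.
#' @param L_list list of V Laplacians.
#' @param rho exponent (> 1).
#' @param eps_trace trace floor.
#' @return Length-V weight vector summing to 1 exactly.
#' @export
update_view_weights <- function(Phi, W, L_list, rho = 2, eps_trace = 1e-12) {
  if (rho <= 1) stop("rho must exceed 1")
  FW <- Phi %*% W
  h <- vapply(L_list, function(L) sum(FW * (L %*% FW)), numeric(1L))
  hc <- pmax(h, eps_trace)
  if (all(h <= eps_trace)) {
    warning("all smoothness traces at the floor; using uniform view weights")
    eta <- rep(1 / length(L_list), length(L_list))
  } else {
    w <- hc^(-1 / (rho - 1))
    eta <- w / sum(w)
  }
  eta / sum(eta)
}

#' Fit the multi-view Laplacian-regularized RBF network
#'
#' The full alternating procedure: standardize the cohort; place centers
#' by k-means and set the shared width; build the design matrix and the
#' per-view similarity graphs and normalized Laplacians on the training
#' rows; initialize the view weights uniformly and the readout at the
#' unregularized closed-form solution; then for `tmax` iterations update
#' the IRLS diagonal, the readout weights (closed-form solve against the
#' currently fused Laplacian), and the view weights (simplex closed form),
#' refreshing the fused Laplacian after each cycle. The objective is
#' recorded at initialization and after every iteration.
#'
#' Prediction for new rows uses only the basis readout; the Laplacians are
#' a training-time smoother and never involve test rows.
#'
#' @param cohort a raw (unstandardized) [cohort_table()].
#' @param control an [mlap_control()] object.
#' @return An object of class `mlaprbfn`: the basis, readout `W`, view
#'   weights `eta`, per-iteration `objective_trace` and `eta_trace`,
#'   scaler, and the control used.
#' @export
mlaprbfn <- function(cohort, control = mlap_control()) {
  stopifnot(inherits(cohort, "cohort_table"),
            inherits(control, "mlap_control"))
  N <- nrow(cohort$X)
  if (control$p > N) {
    stop("p = ", control$p, " hidden nodes but only N = ", N,
         " training rows")
  }
  std <- standardize_cohort(cohort)
  basis <- rbf_basis(std$X, control$p, control$seed)
  Phi <- rbf_design(std$X, basis)
  Y <- std$Y
  graphs <- build_view_graphs(std$X, kernels = control$kernels,
                              gamma = control$gamma)
  L_list <- graphs$L_list
  V <- length(L_list)
  eta <- rep(1 / V, V)

  # Initial readout: unregularized closed form, ridge-jittered if singular
  W <- tryCatch(rbfn_weights(Phi, Y), error = function(e) {
    A <- crossprod(Phi)
    diag(A) <- diag(A) + 1e-10
    solve(A, crossprod(Phi, Y))
  })

  obj <- numeric(control$tmax + 1L)
  obj[1L] <- mlap_objective(Phi, Y, W, L_list, eta, control$lambda1,
                            control$lambda2, control$rho)
  eta_trace <- matrix(NA_real_, control$tmax + 1L, V)
  eta_trace[1L, ] <- eta
  n_iter <- control$tmax
  for (t in seq_len(control$tmax)) {
    g <- update_irls(W, control$eps_irls)
    L_star <- fuse_laplacians(L_list, eta, control$rho)
    W <- update_weights(Phi, Y, L_star, g, control$lambda1, control$lambda2)
    eta <- update_view_weights(Phi, W, L_list, control$rho,
                               control$eps_trace)
    obj[t + 1L] <- mlap_objective(Phi, Y, W, L_list, eta, control$lambda1,
                                  control$lambda2, control$rho)
    eta_trace[t + 1L, ] <- eta
    if (control$early_stop &&
        abs(obj[t] - obj[t + 1L]) < control$tol * max(abs(obj[t]), 1)) {
      n_iter <- t
      break
    }
  }
  obj <- obj[seq_len(n_iter + 1L)]
  eta_trace <- eta_trace[seq_len(n_iter + 1L), , drop = FALSE]

  structure(
    list(basis = basis, W = W, eta = eta, scaler = std$scaler,
         control = control, objective_trace = obj, eta_trace = eta_trace,
         kernels = graphs$kernels,
         column_names = cohort$column_names,
         target_names = cohort$target_names,
         fitted = Phi %*% W, n_iter = n_iter),
    class = "mlaprbfn"
  )
}

#' @export
print.mlaprbfn <- function(x, ...) {
  cat("Multi-view Laplacian-regularized RBF network\n")
  cat("  hidden nodes:", x$basis$p, " sigma:", format(x$basis$sigma), "\n")
  cat("  views (kernels):", paste(x$kernels, collapse = ", "), "\n")
  cat("  eta:", paste(format(x$eta, digits = 4), collapse = ", "), "\n")
  cat("  objective:", format(x$objective_trace[1L]), "->",
      format(x$objective_trace[length(x$objective_trace)]), "over",
      x$n_iter, "iterations\n")
  invisible(x)
}

#' Predict method for the regularized network
#'
#' @param object an [mlaprbfn()] fit.
#' @param newdata raw predictor matrix; the training-fold standardization
#'   is applied internally.
#' @param ... unused.
#' @return Matrix of predictions, one row per row of `newdata`.
#' @export
predict.mlaprbfn <- function(object, newdata, ...) {
  Xs <- apply_scaler(newdata, object$scaler)
  rbf_predict(Xs, object$basis, object$W)
}
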