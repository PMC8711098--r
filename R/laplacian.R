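#' Heat-kernel similarity matrix for one view
#'
#' Builds the N x N patient-similarity matrix for one of the four kernels
#' used as graph views, evaluated on standardized predictors:
#'
#' 1. Gaussian heat kernel \eqn{\exp(-\gamma\|x_i-x_j\|^2)}
#' 2. cosine similarity \eqn{x_i^T x_j / (|x_i||x_j|)}
#' 3. shifted polynomial \eqn{(-\gamma x_i^T x_j + 0.1)^2}
#' 4. sigmoid \eqn{\tanh(-\gamma x_i^T x_j + 0.1)}
#'
#' Kernels 2-4 can take negative values on z-scored data; they are used as
#' printed, without clipping. The result is symmetrized as
#' \eqn{(S + S^T)/2} to remove floating-point asymmetry.
#'
#' @param X numeric matrix N x d of standardized predictors.
#' @param kernel integer in 1..4 selecting the view.
#' @param gamma positive kernel constant (default 1).
#' @return The symmetric N x N similarity matrix.
#' @export
similarity_matrix <- function(X, kernel, gamma = 1) {
  X <- as.matrix(X)
  if (!kernel %in% 1:4) stop("kernel must be one of 1, 2, 3, 4")
  if (gamma <= 0) stop("gamma must be positive")
  G <- tcrossprod(X)
  S <- switch(kernel,
    `1` = {
      sq <- diag(G)
      d2 <- outer(sq, rep(1, length(sq))) + outer(rep(1, length(sq)), sq) -
        2 * G
      d2[d2 < 0] <- 0
      exp(-gamma * d2)
    },
    `2` = {
      nrm <- sqrt(diag(G))
      zero <- which(nrm <= .Machine$double.eps)
      if (length(zero) > 0L) {
        stop("cosine kernel undefined: row ", zero[1L], " has zero norm")
      }
      G / outer(nrm, nrm)
    },
    `3` = (-gamma * G + 0.1)^2,
    `4` = tanh(-gamma * G + 0.1)
  )
  (S + t(S)) / 2
}

#' Normalized graph Laplacian
#'
#' From a symmetric similarity matrix `S`, forms degrees
#' \eqn{D_{ii} = \sum_j |S_{ij}|}, the combinatorial Laplacian
#' \eqn{\Delta = D - S}, and the normalized Laplacian
#' \eqn{L = D^{-1/2} \Delta D^{-1/2}}. For a nonnegative similarity
#' matrix this is the ordinary normalized graph Laplacian (degrees are
#' plain row sums, `Delta` rows sum to zero). Kernels 2-4 can produce
#' negative similarities, making plain row-sum degrees non-positive and
#' the normalized Laplacian unbounded and indefinite; the absolute-value
#' degree is the signed-graph Laplacian convention, which keeps `Delta`
#' and `L` positive semidefinite with the spectrum of `L` in [0, 2] for
#' any sign pattern, so the smoothness traces the solver consumes stay
#' nonnegative. Degrees are floored at `eps_deg` before the inverse
#' square root (only reachable when an entire row of `S` is ~0). The
#' product is symmetrized to remove floating-point asymmetry.
#'
#' @param S symmetric N x N similarity matrix.
#' @param eps_deg degree floor (default 1e-8).
#' @return List with `L` (normalized Laplacian), `Delta` (combinatorial
#'   Laplacian) and `degree` (absolute row sums of `S`).
#' @export
graph_laplacian <- function(S, eps_deg = 1e-8) {
  S <- as.matrix(S)
  if (nrow(S) == 0L) stop("empty similarity matrix")
  if (nrow(S) != ncol(S)) stop("S must be square")
  deg <- rowSums(abs(S))
  Delta <- diag(deg, nrow = length(deg)) - S
  dinv <- 1 / sqrt(pmax(deg, eps_deg))
  L <- Delta * outer(dinv, dinv)
  L <- (L + t(L)) / 2
  list(L = L, Delta = Delta, degree = deg)
}

#' Build all similarity graphs and Laplacians for a training set
#'
#' One view per requested kernel: its similarity matrix and normalized
#' Laplacian. Graphs are built on training rows only; held-out rows never
#' enter the Laplacians (prediction is purely through the basis readout).
#'
#' @param X numeric matrix N x d of standardized training predictors.
#' @param kernels integer subset of 1:4 (default all four views).
#' @param gamma kernel constant.
#' @param eps_deg degree floor passed to [graph_laplacian()].
#' @return An object of class `view_graphs`: lists `S_list` and `L_list`,
#'   the kernel ids, and `gamma`.
#' @export
build_view_graphs <- function(X, kernels = 1:4, gamma = 1, eps_deg = 1e-8) {
  stopifnot(length(kernels) >= 1L, all(kernels %in% 1:4))
  S_list <- lapply(kernels, function(k) similarity_matrix(X, k, gamma))
  L_list <- lapply(S_list, function(S) graph_laplacian(S, eps_deg)$L)
  structure(list(S_list = S_list, L_list = L_list,
                 kernels = as.integer(kernels), gamma = gamma),
            class = "view_graphs")
}

#' Fuse per-view Laplacians with simplex weights
#'
#' \eqn{L^* = \sum_v \eta_v^{\rho} L_v}. The exponent \eqn{\rho > 1} is
#' applied to the view weights, matching the regularizer the solver
#' minimizes.
#'
#' @param L_list list of V Laplacian matrices (all N x N).
#' @param eta numeric vector of V view weights on the simplex.
#' @param rho exponent on the weights (> 1, default 2).
#' @return The fused N x N matrix.
#' @export
fuse_laplacians <- function(L_list, eta, rho = 2) {
  if (length(L_list) != length(eta)) {
    stop("length mismatch: ", length(L_list), " Laplacians but ",
         length(eta), " weights")
  }
  out <- eta[1L]^rho * L_list[[1L]]
  for (v in seq_along(L_list)[-1L]) out <- out + eta[v]^rho * L_list[[v]]
  out
}
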