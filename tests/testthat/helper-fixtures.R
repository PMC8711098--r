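# Shared small fixtures, all generated in code.

# Tiny deterministic regression instance with a well-conditioned design.
tiny_instance <- function(n = 20L, d = 3L, p = 4L, q = 1L, seed = 1L) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d)
  centers <- matrix(rnorm(p * d), p, d)
  basis <- structure(list(centers = centers, sigma = 1.5, p = p),
                     class = "rbf_basis")
  Phi <- rbf_design(X, basis)
  W_true <- matrix(rnorm(p * q), p, q)
  Y <- Phi %*% W_true + 0.01 * matrix(rnorm(n * q), n, q)
  list(X = X, basis = basis, Phi = Phi, Y = Y, W_true = W_true)
}

# Random symmetric PSD matrix.
random_psd <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n, n)
  crossprod(A) / n
}

# Numerical minimizer of sum(eta^rho * h) over the open probability
# simplex, independent of the closed-form update (free parameters are the
# first V-1 coordinates, last one by difference, big penalty off-simplex).
simplex_minimize <- function(h, rho) {
  V <- length(h)
  fn <- function(par) {
    eta <- c(par, 1 - sum(par))
    if (any(eta <= 1e-9)) return(1e9 + sum(par^2))
    sum(eta^rho * h)
  }
  fit <- stats::optim(rep(1 / V, V - 1L), fn, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 50000))
  eta <- c(fit$par, 1 - sum(fit$par))
  eta / sum(eta)
}
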