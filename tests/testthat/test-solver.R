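test_that("the objective reduces correctly in its degenerate corners", {
  inst <- tiny_instance(seed = 2)
  Ls <- lapply(1:3, function(s) random_psd(20, seed = s))
  eta <- c(0.2, 0.5, 0.3)
  # W = 0: only the data term survives
  W0 <- matrix(0, 4, 1)
  expect_equal(mlap_objective(inst$Phi, inst$Y, W0, Ls, eta, 1, 7),
               0.5 * sum(inst$Y^2))
  # both penalties off: plain half squared error
  W <- inst$W_true
  expect_equal(mlap_objective(inst$Phi, inst$Y, W, Ls, eta, 0, 0),
               0.5 * norm(inst$Phi %*% W - inst$Y, "F")^2)
})

test_that("the objective matches a term-by-term loop evaluation", {
  inst <- tiny_instance(seed = 3, q = 2)
  Ls <- lapply(1:2, function(s) random_psd(20, seed = 10 + s))
  eta <- c(0.6, 0.4); l1 <- 0.3; l2 <- 0.7; rho <- 2.5
  W <- inst$W_true
  FW <- inst$Phi %*% W
  fit <- 0
  for (i in 1:20) for (j in 1:2) fit <- fit + (FW[i, j] - inst$Y[i, j])^2
  lap <- 0
  for (v in 1:2) lap <- lap +
    eta[v]^rho * sum(diag(t(FW) %*% Ls[[v]] %*% FW))
  l21 <- 0
  for (j in 1:4) l21 <- l21 + sqrt(sum(W[j, ]^2))
  expect_equal(mlap_objective(inst$Phi, inst$Y, W, Ls, eta, l1, l2, rho),
               0.5 * fit + 0.5 * l1 * lap + 0.5 * l2 * l21,
               tolerance = 1e-10)
})

test_that("the IRLS diagonal is the half inverse row norm with a zero-row guard", {
  W <- rbind(c(3, 4), c(0, 0), c(1, 0))
  g <- update_irls(W, eps_irls = 1e-8)
  expect_equal(g[1], 0.1)               # ||(3,4)|| = 5
  expect_equal(g[2], 1 / (2 * 1e-8))    # guarded zero row
  expect_equal(g[3], 0.5)
  set.seed(6)
  Wr <- matrix(rnorm(12), 4, 3)
  expect_equal(update_irls(Wr), sapply(1:4, function(j)
    1 / (2 * sqrt(sum(Wr[j, ]^2)))))
})

test_that("the readout update solves its stationarity system and reduces to least squares", {
  inst <- tiny_instance(seed = 5)
  L_star <- random_psd(20, seed = 21)
  g <- rep(0.3, 4)
  W <- update_weights(inst$Phi, inst$Y, L_star, g, 0.2, 0.4)
  A <- crossprod(inst$Phi) + 0.2 * t(inst$Phi) %*% L_star %*% inst$Phi +
    0.4 * diag(g)
  expect_lt(norm(A %*% W - crossprod(inst$Phi, inst$Y), "F"),
            1e-8 * norm(crossprod(inst$Phi, inst$Y), "F"))
  # with both penalties off this is the closed-form baseline readout
  W00 <- update_weights(inst$Phi, inst$Y, L_star, g, 0, 0)
  expect_equal(W00, rbfn_weights(inst$Phi, inst$Y), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("the readout update beats random perturbations of the surrogate", {
  set.seed(30)
  inst <- tiny_instance(n = 30, d = 3, p = 5, seed = 30)
  L_star <- random_psd(30, seed = 31)
  g <- runif(5, 0.1, 1)
  l1 <- 0.3; l2 <- 0.5
  W <- update_weights(inst$Phi, inst$Y, L_star, g, l1, l2)
  surrogate <- function(W) {
    FW <- inst$Phi %*% W
    0.5 * sum((FW - inst$Y)^2) + 0.5 * l1 * sum(FW * (L_star %*% FW)) +
      0.5 * l2 * sum(g * rowSums(W^2))
  }
  j0 <- surrogate(W)
  for (i in 1:1000) {
    expect_lte(j0, surrogate(W + matrix(rnorm(5, 0, 0.05), 5, 1)) + 1e-12)
  }
})

test_that("the view-weight update is exact in its closed-form corners", {
  L <- random_psd(6, seed = 40)
  Phi <- diag(6); W <- matrix(rnorm(6), 6, 1)
  # identical views: uniform weights by symmetry
  eta <- update_view_weights(Phi, W, list(L, L, L), rho = 2)
  expect_equal(eta, rep(1 / 3, 3))
  # traces (1, 4) at rho = 2: eta proportional to (1, 1/4)
  eta2 <- update_view_weights(matrix(1), matrix(1),
                              list(matrix(1), matrix(4)), rho = 2)
  expect_equal(eta2, c(0.8, 0.2))
  expect_equal(sum(eta2), 1)
  expect_error(update_view_weights(Phi, W, list(L), rho = 1), "exceed")
})

test_that("the view-weight update matches a numerical simplex minimizer", {
  set.seed(50)
  Phi <- matrix(rnorm(30), 10, 3)
  W <- matrix(rnorm(3), 3, 1)
  Ls <- lapply(1:3, function(s) random_psd(10, seed = 50 + s))
  FW <- Phi %*% W
  h <- sapply(Ls, function(L) sum(FW * (L %*% FW)))
  eta_closed <- update_view_weights(Phi, W, Ls, rho = 2)
  eta_num <- simplex_minimize(h, rho = 2)
  expect_equal(eta_closed, eta_num, tolerance = 1e-5)
})

test_that("large rho flattens the view weights toward uniform", {
  h <- c(0.5, 1.2, 3.0, 8.0)
  Phi <- matrix(1); W <- matrix(1)
  Ls <- lapply(h, function(x) matrix(x))
  entropy <- function(eta) -sum(eta * log(eta))
  ents <- sapply(c(1.1, 2, 4, 16), function(rho)
    entropy(update_view_weights(Phi, W, Ls, rho = rho)))
  expect_true(all(diff(ents) > 0))
  eta16 <- update_view_weights(Phi, W, Ls, rho = 16)
  expect_lt(max(abs(eta16 - 0.25)), 0.05)
})

test_that("fusing V identical views equals V^(1-rho) times one view exactly", {
  L <- random_psd(7, seed = 60)
  for (V in c(1, 2, 4)) {
    expect_equal(fuse_laplacians(rep(list(L), V), rep(1 / V, V), rho = 2),
                 V^(1 - 2) * L)
    expect_equal(fuse_laplacians(rep(list(L), V), rep(1 / V, V), rho = 3),
                 V^(1 - 3) * L)
  }
})

test_that("with both penalties off the solver reproduces the plain network", {
  co <- generate_multiview_fixture(n = 50, d = 3, seed = 17)
  ctl <- mlap_control(p = 8, lambda1 = 0, lambda2 = 0, seed = 5)
  fitM <- mlaprbfn(co, ctl)
  fitR <- rbfn(co, p = 8, seed = 5)
  expect_equal(fitM$W, fitR$W, tolerance = 1e-8)
  expect_equal(predict(fitM, co$X), predict(fitR, co$X), tolerance = 1e-6)
})

test_that("the objective trace is non-increasing and the weights stay on the simplex", {
  for (s in 1:5) {
    co <- generate_multiview_fixture(n = 60, d = 3, seed = s)
    fit <- mlaprbfn(co, mlap_control(p = 8, seed = s))
    tr <- fit$objective_trace
    expect_equal(length(tr), 11L)  # init + tmax iterations
    rel <- diff(tr) / pmax(abs(tr[-length(tr)]), .Machine$double.xmin)
    expect_lt(max(rel), 1e-9)
    for (t in seq_len(nrow(fit$eta_trace))) {
      eta <- fit$eta_trace[t, ]
      expect_lt(abs(sum(eta) - 1), 1e-12)
      expect_true(all(eta > 0 & eta < 1))
    }
  }
})

test_that("regularization lowers cross-validated error in a noisy overparameterized regime", {
  # smooth target, substantial noise, generous center budget: the setting
  # where the graph smoother and row sparsity should pay off
  wins <- 0L
  for (s in 1:10) {
    co <- generate_multiview_fixture(n = 60, d = 3, noise_sd = 0.3, seed = s)
    ctl <- mlap_control(p = 20)
    cvM <- kfold_cv(co, k = 10, seed = s, model = "mlaprbfn", control = ctl)
    cvR <- kfold_cv(co, k = 10, seed = s, model = "rbfn", control = ctl)
    wins <- wins + (cvM$metrics$rmse <= cvR$metrics$rmse)
  }
  expect_gte(wins, 7L)
})
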