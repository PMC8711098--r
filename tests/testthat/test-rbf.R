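test_that("k-means center selection recovers well-separated cloud means", {
  set.seed(3)
  cloud1 <- matrix(rnorm(100, 0, 0.05), 50, 2)
  cloud2 <- matrix(rnorm(100, 5, 0.05), 50, 2)
  ctr <- select_centers(rbind(cloud1, cloud2), p = 2, seed = 9)
  ctr <- ctr[order(ctr[, 1]), ]
  expect_lt(max(abs(ctr[1, ] - colMeans(cloud1))), 0.1)
  expect_lt(max(abs(ctr[2, ] - colMeans(cloud2))), 0.1)
})

test_that("center selection handles the p = N fixed point and bad p", {
  set.seed(5)
  X <- matrix(rnorm(12), 4, 3)
  ctr <- select_centers(X, p = 4, seed = 1)
  expect_equal(ctr[order(ctr[, 1]), ], unname(X[order(X[, 1]), ]))
  expect_error(select_centers(X, p = 5, seed = 1), "only N = 4")
  expect_error(select_centers(X, p = 1, seed = 1), "at least 2")
})

test_that("center selection is deterministic for fixed (X, p, seed)", {
  set.seed(8)
  X <- matrix(rnorm(200), 50, 4)
  expect_identical(select_centers(X, 7, seed = 11),
                   select_centers(X, 7, seed = 11))
})

test_that("the shared width is the maximum center distance over sqrt(2p)", {
  # two centers at distance 2: sigma = 2 / sqrt(4) = 1
  expect_equal(rbf_width(rbind(c(0, 0), c(2, 0))), 1)
  # three collinear centers at 0, 1, 3: brute-force max over all pairs is 3
  ctrs <- cbind(c(0, 1, 3))
  d_brute <- max(apply(expand.grid(1:3, 1:3), 1,
                       function(ij) abs(ctrs[ij[1]] - ctrs[ij[2]])))
  expect_equal(rbf_width(ctrs), d_brute / sqrt(6))
  # the rule at the selected node count p = 140
  set.seed(2)
  C140 <- matrix(rnorm(140 * 7), 140, 7)
  expect_equal(rbf_width(C140), max(dist(C140)) / sqrt(280))
  expect_error(rbf_width(matrix(1, 3, 2)), "coincide")
  expect_error(rbf_width(matrix(1, 1, 2)), "at least 2")
})

test_that("design matrix matches the Gaussian activation entrywise", {
  basis <- structure(list(centers = rbind(c(0, 0), c(3, 4)), sigma = 2),
                     class = "rbf_basis")
  Phi <- rbf_design(rbind(c(0, 0), c(2 * sqrt(2), 0)), basis)
  expect_equal(Phi[1, 1], 1)                # coincident point
  expect_equal(Phi[2, 1], exp(-1))          # distance sigma * sqrt(2)
  # brute-force double loop on a random instance
  set.seed(7)
  X <- matrix(rnorm(15), 5, 3)
  C <- matrix(rnorm(12), 4, 3)
  b2 <- structure(list(centers = C, sigma = 0.9), class = "rbf_basis")
  Phi2 <- rbf_design(X, b2)
  for (i in 1:5) for (j in 1:4) {
    expect_equal(Phi2[i, j],
                 exp(-sum((X[i, ] - C[j, ])^2) / (2 * 0.9^2)),
                 tolerance = 1e-12)
  }
  expect_true(all(Phi2 > 0 & Phi2 <= 1))
  expect_error(rbf_design(X, list(centers = C, sigma = 0)), "positive")
  expect_error(rbf_design(X[, 1:2], b2), "mismatch")
})

test_that("closed-form readout solves the normal equations", {
  # identity design: weights are the targets
  Y <- matrix(c(1, 2, 3))
  expect_equal(rbfn_weights(diag(3), Y), Y, ignore_attr = TRUE)
  # square invertible design interpolates
  set.seed(1)
  Phi <- diag(4) + 0.1 * matrix(runif(16), 4, 4)
  Yq <- matrix(rnorm(4))
  W <- rbfn_weights(Phi, Yq)
  expect_lt(norm(Phi %*% W - Yq, "F"), 1e-8)
  # overdetermined system matches an independent least-squares oracle
  inst <- tiny_instance(n = 20, p = 3, seed = 4)
  W2 <- rbfn_weights(inst$Phi, inst$Y)
  W_ls <- qr.solve(inst$Phi, inst$Y)
  expect_equal(W2, W_ls, tolerance = 1e-10, ignore_attr = TRUE)
  # residual orthogonal to the column space
  expect_lt(norm(crossprod(inst$Phi, inst$Phi %*% W2 - inst$Y), "F"),
            1e-8 * norm(crossprod(inst$Phi, inst$Y), "F"))
  # rank-deficient Gram matrix is an error, not a silent ridge
  expect_error(rbfn_weights(cbind(1:4, 1:4), matrix(1:4)), "rank-deficient")
})

test_that("prediction reuses the training design consistently", {
  inst <- tiny_instance(seed = 6)
  W <- rbfn_weights(inst$Phi, inst$Y)
  # a training row predicts its fitted value
  pred <- rbf_predict(inst$X[3, , drop = FALSE], inst$basis, W)
  expect_equal(pred[1, 1], (inst$Phi %*% W)[3, 1], tolerance = 1e-12)
  # batch invariance
  batch <- rbf_predict(inst$X[c(3, 7, 3), ], inst$basis, W)
  expect_equal(batch[1, ], batch[3, ])
  # manual matrix product oracle
  Xn <- matrix(c(0.2, -0.1, 0.4), 1, 3)
  manual <- rbf_design(Xn, inst$basis) %*% W
  expect_equal(rbf_predict(Xn, inst$basis, W), manual)
})

test_that("the full pipeline is bit-identical across repeated runs", {
  co <- generate_multiview_fixture(n = 40, seed = 13)
  f1 <- rbfn(co, p = 6, seed = 2)
  f2 <- rbfn(co, p = 6, seed = 2)
  expect_identical(f1$basis$centers, f2$basis$centers)
  expect_identical(f1$W, f2$W)
  expect_identical(predict(f1, co$X), predict(f2, co$X))
})
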