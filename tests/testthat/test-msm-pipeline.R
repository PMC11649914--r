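test_that("cross-domain featurization enumerates strided Calpha pairs", {
  atoms <- data.frame(resid = 1:12, resname = "ALA", name = "CA",
                      is_water = FALSE, is_sidechain = FALSE)
  set.seed(2)
  P <- matrix(runif(36) * 10, ncol = 3)
  tr <- make_traj(list(P, P + 5), atoms = atoms)   # rigid translation
  X <- featurize_interdomain_distances(tr, 1:6, 7:12, stride = 2)
  expect_equal(ncol(X), 9)  # 3 x 3 strided atoms
  ## rigid translation leaves every feature unchanged
  expect_equal(X[1, ], X[2, ], ignore_attr = TRUE)
  ## values equal brute-force distances
  ia <- attr(X, "selA"); ib <- attr(X, "selB")
  want <- as.numeric(t(outer(ia, ib, Vectorize(function(i, j)
    sqrt(sum((P[i, ] - P[j, ])^2))))))
  expect_equal(as.numeric(X[1, ]), want, tolerance = 1e-12)
  expect_error(featurize_interdomain_distances(tr, 99, 7:12), "empty")
})

test_that("tICA identifies slow directions and is whitened at lag zero", {
  ## two AR(1) processes with very different correlation times
  set.seed(14)
  n <- 20000
  slow <- stats::filter(rnorm(n), 0.99, "recursive")
  fast <- stats::filter(rnorm(n), 0.2, "recursive")
  X <- cbind(slow, fast) %*% matrix(c(0.8, 0.6, -0.6, 0.8), 2)
  tica <- tica_fit(X, lag = 20, n_components = 2)
  Y <- predict(tica, X)
  ## tIC1 aligns with the slow coordinate
  expect_gt(abs(cor(Y[, 1], as.numeric(slow))), 0.99)
  ## projections are uncorrelated with unit variance at lag 0
  C <- crossprod(sweep(Y, 2, colMeans(Y))) / (nrow(Y) - 0)
  expect_equal(C, diag(2), tolerance = 0.05)
  ## lag-symmetric white noise: eigenvalues near zero
  W <- matrix(rnorm(4000), ncol = 2)
  t0 <- tica_fit(W, lag = 5)
  expect_lt(max(abs(t0$eigenvalues)), 0.1)
  ## small instance equals a brute-force generalized eigendecomposition
  set.seed(4)
  S <- matrix(rnorm(900), ncol = 3)
  lag <- 7
  tfit <- tica_fit(S, lag = lag, shrinkage = 0)
  n2 <- nrow(S)
  Sc <- sweep(S, 2, colMeans(S))
  X0 <- Sc[1:(n2 - lag), ]; Xt <- Sc[(1 + lag):n2, ]
  m <- nrow(X0)
  C0 <- (crossprod(X0) + crossprod(Xt)) / (2 * m)
  Ct <- (crossprod(X0, Xt) + crossprod(Xt, X0)) / (2 * m)
  ev_oracle <- sort(Re(eigen(solve(C0, Ct))$values), decreasing = TRUE)
  expect_equal(tfit$eigenvalues, ev_oracle, tolerance = 1e-8)
})

test_that("k-means microstates separate well-separated blobs deterministically", {
  set.seed(6)
  Y <- rbind(matrix(rnorm(200, 0, 0.1), ncol = 2),
             matrix(rnorm(200, 5, 0.1), ncol = 2),
             matrix(rnorm(200, -5, 0.1), ncol = 2))
  d1 <- cluster_microstates(Y, k = 3, seed = 2)
  expect_equal(length(unique(d1[1:100])), 1)
  expect_equal(length(unique(d1[101:200])), 1)
  expect_equal(length(unique(d1[201:300])), 1)
  expect_identical(as.integer(d1), as.integer(cluster_microstates(Y, 3, seed = 2)))
  ## inertia no worse than a random assignment
  km <- attr(d1, "kmeans")
  set.seed(1)
  rand_assign <- sample(1:3, nrow(Y), replace = TRUE)
  rand_inertia <- sum(vapply(1:3, function(k) {
    pts <- Y[rand_assign == k, , drop = FALSE]
    sum(sweep(pts, 2, colMeans(pts))^2)
  }, numeric(1)))
  expect_lte(km$tot.withinss, rand_inertia)
  expect_error(cluster_microstates(Y, k = 1000), "exceeds")
})

test_that("reversible MSM estimation matches closed forms and the MLE oracle", {
  ## symmetric counts give the obvious chain
  d <- c(rep(c(rep(1, 9), rep(2, 9)), 30))
  C <- matrix(c(90, 10, 10, 90), 2, byrow = TRUE)
  ## build a dtraj realizing exactly these counts is awkward; test the
  ## estimator on counts via a symmetric two-state trajectory instead
  msm <- estimate_reversible_msm(d, lag = 1)
  expect_equal(msm$pi, c(0.5, 0.5), tolerance = 0.02)
  expect_true(all(abs(rowSums(msm$T) - 1) < 1e-12))
  ## detailed balance to 1e-8 and stationary left eigenvector to 1e-10
  flux <- diag(msm$pi) %*% msm$T
  expect_lt(max(abs(flux - t(flux))), 1e-8)
  expect_lt(max(abs(msm$pi %*% msm$T - msm$pi)), 1e-10)
  ## asymmetric counts: compare with brute-force constrained optimization
  set.seed(8)
  d2 <- integer(4000)
  T_true <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  d2[1] <- 1
  for (i in 2:4000) d2[i] <- sample(1:2, 1, prob = T_true[d2[i - 1], ])
  msm2 <- estimate_reversible_msm(d2, lag = 1)
  C2 <- matrix(0, 2, 2)
  for (i in 2:4000) C2[d2[i - 1], d2[i]] <- C2[d2[i - 1], d2[i]] + 1
  ## oracle: maximize likelihood over reversible 2-state chains
  ## parameterized by (p = T12, pi1); T21 = pi1 p / (1 - pi1)
  nll <- function(par) {
    p <- plogis(par[1]); pi1 <- plogis(par[2])
    q <- pi1 * p / (1 - pi1)
    if (q >= 1) return(1e10)
    -(C2[1, 1] * log(1 - p) + C2[1, 2] * log(p) +
        C2[2, 1] * log(q) + C2[2, 2] * log(1 - q))
  }
  opt <- optim(c(0, 0), nll)
  p_hat <- plogis(opt$par[1])
  expect_equal(msm2$T[1, 2], p_hat, tolerance = 1e-3)
  ## disconnected data restricted with a message
  d3 <- c(rep(1:2, 50), rep(c(3L, 4L), 50) + 0L)
  d3 <- list(rep(1:2, 50), rep(3:4, 10))
  expect_message(m3 <- estimate_reversible_msm(d3, lag = 1), "largest")
  expect_equal(nrow(m3$T), 2)
})

test_that("implied timescales follow the closed form and plateau on Markov data", {
  ## two-state chain with lambda2 = 0.8 at unit lag: t2 = -1/log(0.8)
  set.seed(10)
  T_true <- matrix(c(0.9, 0.1, 0.1, 0.9), 2)  # lambda2 = 0.8
  d <- integer(60000); d[1] <- 1
  for (i in 2:60000) d[i] <- sample(1:2, 1, prob = T_true[d[i - 1], ])
  msm <- estimate_reversible_msm(d, lag = 1)
  ev <- sort(eigen(msm$T, only.values = TRUE)$values, decreasing = TRUE)
  expect_equal(-1 / log(ev[2]), -1 / log(0.8), tolerance = 0.15)
  ## Markovian data: flat timescales across lags
  its <- implied_timescales(d, lags = c(1, 2, 4, 8), n_its = 1)
  t1 <- its$timescales$t1
  expect_lt(max(abs(t1 - t1[1])) / t1[1], 0.25)
  expect_true(its$plateau)
  ## white noise: no finite slow timescale resolved
  dn <- sample(1:4, 20000, replace = TRUE)
  itn <- implied_timescales(dn, lags = c(1, 2, 4), n_its = 1)
  expect_true(all(is.na(itn$timescales$t1) | itn$timescales$t1 < 3))
})

test_that("PCCA+ gives crisp memberships on block structure and valid rows always", {
  ## nearly block-diagonal 3-block chain
  eps <- 1e-3
  B <- matrix(eps, 6, 6)
  blocks <- list(1:2, 3:4, 5:6)
  for (b in blocks) B[b, b] <- 0.5
  T_ <- B / rowSums(B)
  ## symmetric by construction: pi uniform
  msm <- structure(list(T = T_, pi = rep(1 / 6, 6), lag = 1,
                        active_set = 1:6), class = "msm_model")
  p <- pcca_coarse_grain(msm, 3)
  expect_true(all(abs(rowSums(p$memberships) - 1) < 1e-9))
  expect_true(all(p$memberships >= 0 & p$memberships <= 1))
  crisp <- p$assignment
  for (b in blocks) expect_length(unique(crisp[b]), 1)
  expect_equal(sort(p$macro_pi), rep(1 / 3, 3), tolerance = 0.01)
  expect_equal(sum(p$macro_pi), 1, tolerance = 1e-12)
})

test_that("CK test validates Markovian data and flags non-Markovian data", {
  set.seed(3)
  T_true <- matrix(c(0.95, 0.05, 0, 0.05, 0.9, 0.05, 0, 0.05, 0.95), 3,
                   byrow = TRUE)
  d <- integer(50000); d[1] <- 1
  for (i in 2:50000) d[i] <- sample(1:3, 1, prob = T_true[d[i - 1], ])
  msm <- estimate_reversible_msm(d, lag = 1)
  ck <- ck_test(msm, d, n_sets = 3, steps = 1:5)
  ## k = 1 agrees closely by construction, all steps within sampling noise
  expect_lt(max(abs(ck$curves$predicted[ck$curves$k == 1] -
                      ck$curves$estimated[ck$curves$k == 1])), 0.02)
  expect_lt(ck$max_dev, 0.05)
  ## deliberately non-Markovian: a semi-deterministic alternation with
  ## long memory (period-two structure at the coarse level)
  dn <- rep(c(rep(1L, 20), rep(2L, 2), rep(3L, 20), rep(2L, 2)), 500)
  msn <- estimate_reversible_msm(dn, lag = 1)
  ckn <- ck_test(msn, dn, n_sets = 2, steps = c(1, 10, 20))
  expect_gt(ckn$max_dev, 0.1)
})

test_that("weighted FES reproduces the generating potential and is shift-invariant", {
  pot <- double_well_1d(barrier = 6)
  tr <- langevin_sample(pot, langevin_params(n_steps = 2e6, dt = 1e-3,
                                             seed = 17, stride = 4))
  Y <- cbind(tr[, 1], tr[, 1] * 0)  # 1D data embedded for the 2D histogram
  dtraj <- cluster_microstates(Y, k = 30, seed = 5)
  msm <- estimate_reversible_msm(dtraj, lag = 25)
  fes <- weighted_fes(Y, msm, dtraj, bins = 40, kT = 2.579)
  Fx <- apply(fes$F, 1, min, na.rm = TRUE)
  sampled <- is.finite(Fx)
  want <- pot$U(fes$x[sampled]) - min(pot$U(fes$x[sampled]))
  dev <- (Fx[sampled] - want) - mean(Fx[sampled] - want)
  ## 0.5 kT agreement where sampled
  expect_lt(max(abs(dev[want < 6])), 0.5 * 2.579)
  ## uniform weights on uniform data give a flat surface
  set.seed(2)
  Yu <- cbind(runif(20000), runif(20000))
  du <- cluster_microstates(Yu, k = 10, seed = 3)
  msu <- estimate_reversible_msm(du, lag = 1)
  fu <- weighted_fes(Yu, msu, du, bins = 5, kT = 1)
  expect_lt(max(fu$F, na.rm = TRUE), 0.2)
})

test_that("adaptive seeding returns nearest frames with index tie-breaks", {
  Y <- rbind(c(0, 0), c(1, 1), c(0.1, 0), c(1, 1))
  expect_equal(adaptive_seed_selection(Y, c(0, 0), 2), c(1L, 3L))
  ## exact tie between frames 2 and 4: lower index first
  expect_equal(adaptive_seed_selection(Y, c(1, 1), 2), c(2L, 4L))
  ## matches a brute-force nearest-neighbour oracle
  set.seed(20)
  Yr <- matrix(rnorm(200), ncol = 2)
  target <- c(0.3, -0.2)
  got <- adaptive_seed_selection(Yr, target, 5)
  d2 <- rowSums(sweep(Yr, 2, target)^2)
  expect_equal(got, order(d2)[1:5])
})
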