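test_that("normalized covariance is symmetric with unit trace", {
  # D = identity: D D' = I, trace 2
  expect_equal(unclass(normalized_covariance(diag(2))),
               matrix(c(0.5, 0, 0, 0.5), 2), ignore_attr = TRUE)
  set.seed(8)
  for (i in 1:10) {
    D <- matrix(rnorm(6 * 50), 6, 50)
    C <- normalized_covariance(D)
    expect_equal(sum(diag(C)), 1)
    expect_equal(unclass(C), t(unclass(C)), ignore_attr = TRUE)
  }
  # an all-zero row among nonzero rows stays valid: its row/column is zero
  D <- rbind(rnorm(30), 0, rnorm(30))
  C <- normalized_covariance(D)
  expect_equal(unname(C[2, ]), rep(0, 3))
  expect_equal(unname(C[, 2]), rep(0, 3))
  expect_error(normalized_covariance(matrix(0, 3, 10)), "zero trace")
  expect_error(normalized_covariance(matrix(1, 3, 1)), "2 samples")
})

test_that("class-mean covariance is the element-wise mean and keeps unit trace", {
  set.seed(3)
  C <- normalized_covariance(matrix(rnorm(20), 2, 10))
  expect_equal(unclass(class_mean_covariance(list(C, C))), unclass(C),
               ignore_attr = TRUE)
  A <- matrix(c(0.7, 0.1, 0.1, 0.3), 2)
  B <- matrix(c(0.5, -0.2, -0.2, 0.5), 2)
  expect_equal(unclass(class_mean_covariance(list(A, B))),
               matrix(c(0.6, -0.05, -0.05, 0.4), 2), ignore_attr = TRUE)
  covs <- lapply(1:5, function(i) normalized_covariance(matrix(rnorm(40), 4, 10)))
  expect_equal(sum(diag(class_mean_covariance(covs))), 1)
  expect_error(class_mean_covariance(list()), "empty")
})

test_that("CSP on contrasting diagonal covariances recovers the axis filters", {
  m <- fit_csp(diag(c(0.8, 0.2)), diag(c(0.2, 0.8)))
  expect_equal(m$lambda1, c(0.8, 0.2))
  expect_equal(m$lambda2, c(0.2, 0.8))
  expect_equal(m$lambda1 + m$lambda2, c(1, 1))
  expect_equal(abs(m$W), diag(2), tolerance = 1e-12)
})

test_that("paired CSP eigenvalues always sum to one and whitening is exact", {
  set.seed(12)
  for (i in 1:100) {
    n <- sample(2:16, 1)
    m <- fit_csp(rand_spd(n), rand_spd(n))
    expect_lt(max(abs(m$lambda1 + m$lambda2 - 1)), 1e-8)
    expect_lt(max(abs(m$P %*% m$Cc %*% t(m$P) - diag(n))), 1e-8)
    expect_equal(sort(m$lambda1, decreasing = TRUE), m$lambda1)
    expect_equal(qr(m$W)$rank, n)
  }
})

test_that("CSP eigenvalues match an independent generalized eigensolve", {
  set.seed(44)
  for (i in 1:20) {
    C1 <- rand_spd(4)
    C2 <- rand_spd(4)
    m <- fit_csp(C1, C2)
    # brute force: eigenvalues of (C1 + C2)^-1 C1, no whitening involved
    oracle <- sort(Re(eigen(solve(C1 + C2, C1))$values), decreasing = TRUE)
    expect_lt(max(abs(m$lambda1 - oracle)), 1e-8)
  }
})

test_that("the leading CSP filter maximizes the preictal variance ratio", {
  set.seed(15)
  C1 <- rand_spd(5)
  C2 <- rand_spd(5)
  m <- fit_csp(C1, C2)
  ratio <- function(w) as.numeric((w %*% C1 %*% w) / (w %*% (C1 + C2) %*% w))
  top <- ratio(m$W[1, ])
  expect_equal(top, m$lambda1[1], tolerance = 1e-10)
  for (i in 1:500) {
    w <- rnorm(5)
    expect_lte(ratio(w / sqrt(sum(w^2))), top + 1e-8)
  }
})

test_that("CSP is invariant to simultaneous channel permutation", {
  set.seed(23)
  C1 <- rand_spd(6)
  C2 <- rand_spd(6)
  perm <- sample(6)
  Pm <- diag(6)[perm, ]
  m <- fit_csp(C1, C2)
  mp <- fit_csp(Pm %*% C1 %*% t(Pm), Pm %*% C2 %*% t(Pm))
  expect_equal(mp$lambda1, m$lambda1, tolerance = 1e-10)
  # W_p undoes the permutation: rows agree up to sign
  expect_equal(abs(mp$W %*% Pm), abs(m$W), tolerance = 1e-8)
})

test_that("projection applies the spatial filters row-wise", {
  set.seed(6)
  X <- matrix(rnorm(2 * 20), 2, 20)
  expect_equal(csp_project(X, diag(2)), X)
  P <- rbind(c(0, 1), c(1, 0))
  expect_equal(csp_project(X, P), X[2:1, ])
  W <- matrix(c(1, 2, 3, 4), 2, byrow = TRUE)
  expect_equal(csp_project(X, W), W %*% X)
  expect_error(csp_project(matrix(0, 3, 5), diag(2)), "dimension mismatch")
})

test_that("log-variance features follow the log identities and channel count", {
  set.seed(9)
  x <- rnorm(500)
  x <- (x - mean(x)) / sd(x)  # sample variance exactly 1
  expect_equal(log_variance_features(rbind(x, x))[1], 0, tolerance = 1e-12)
  Y <- matrix(rnorm(23 * 768), 23, 768)
  expect_length(log_variance_features(Y), 23L)
  f1 <- log_variance_features(Y)
  f2 <- log_variance_features(Y * 3)
  expect_equal(f2 - f1, rep(2 * log(3), 23))
  expect_error(log_variance_features(rbind(rep(1, 10), rnorm(10))), "zero variance")
})

test_that("the cross-product fast path reproduces the per-epoch feature route", {
  set.seed(77)
  rec <- recording(matrix(rnorm(4 * 600), 4, 600), fs = 20, record_id = "fp")
  es <- sliding_epochs(rec, segmentation_config(window_s = 3, step_s = 1))
  C1 <- rand_spd(4)
  C2 <- rand_spd(4)
  m <- fit_csp(C1, C2)
  slow <- csp_features(es, m)
  xp <- cspseizure:::.epoch_xprods(es)
  fast <- cspseizure:::.features_from_xprods(m$W, xp)
  expect_equal(fast, slow, tolerance = 1e-10)
  mc <- cspseizure:::.mean_cov_from_xprods(xp, 1:10)
  covs <- lapply(1:10, function(i) normalized_covariance(epoch_matrix(es, i)))
  expect_equal(unclass(mc), unclass(class_mean_covariance(covs)),
               ignore_attr = TRUE, tolerance = 1e-12)
})
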