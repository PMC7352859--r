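std <- function(m) {
  s <- scale(m)
  attr(s, "scaled:center") <- attr(s, "scaled:scale") <- NULL
  s
}

test_that("duplicated sides with no sparsity give canonical correlation 1", {
  set.seed(61)
  x <- std(cbind(rnorm(20), rnorm(20)))
  fit <- fit_scca(x, x, penalty_u = sqrt(2), penalty_v = sqrt(2))
  expect_equal(fit$canonical_correlation, 1, tolerance = 1e-6)
})

test_that("model invariants hold: feasibility and correlation identity", {
  set.seed(62)
  for (pu in c(1, 1.5, 2.2)) {
    X <- std(matrix(rnorm(40 * 6), 40, 6))
    y <- rep(0:1, each = 20)
    Y <- group_indicator_matrix(y)
    fit <- fit_scca(X, Y, penalty_u = pu)
    expect_lte(sqrt(sum(fit$u^2)), 1 + 1e-6)
    expect_lte(sqrt(sum(fit$v^2)), 1 + 1e-6)
    expect_lte(sum(abs(fit$u)), pu + 1e-6)
    expect_lte(sum(abs(fit$v)), fit$penalty_v + 1e-6)
    expect_equal(fit$canonical_correlation,
                 cor(X %*% fit$u, Y %*% fit$v)[1], tolerance = 1e-6)
    # monotone objective path
    if (length(fit$objective_path) > 1)
      expect_true(all(diff(fit$objective_path) > -1e-9))
  }
})

test_that("penalty 1 selects exactly the single best marker", {
  set.seed(63)
  X <- std(matrix(rnorm(50 * 5), 50, 5))
  y <- rep(0:1, each = 25)
  Y <- group_indicator_matrix(y)
  fit <- fit_scca(X, Y, penalty_u = 1)
  expect_identical(sum(fit$u != 0), 1L)
  # enumeration oracle: the chosen coordinate maximizes |u' M v| over
  # all single-coordinate u with the optimal v response
  M <- crossprod(X, Y)
  best <- vapply(1:5, function(j) {
    w <- M[j, ]
    sqrt(sum(w^2))        # objective with u = e_j (sign-optimal), v = w/|w|
  }, 1.0)
  expect_equal(unname(which(fit$u != 0)), which.max(best))
})

test_that("the attained objective matches a brute-force grid oracle", {
  set.seed(64)
  for (rep in 1:4) {
    X <- std(matrix(rnorm(12 * 3), 12, 3))
    Y <- std(matrix(rnorm(12 * 2), 12, 2))
    cu <- c(1.3, sqrt(3))[(rep %% 2) + 1]
    fit <- fit_scca(X, Y, penalty_u = cu, penalty_v = sqrt(2))
    M <- crossprod(X, Y)
    scale_f <- sqrt(sum(M^2))
    oracle <- scca_objective_oracle(M / scale_f, cu, sqrt(2))
    expect_equal(fit$d / scale_f, oracle, tolerance = 1e-4)
  }
})

test_that("with no sparsity and orthogonal columns the fit matches classical CCA", {
  set.seed(65)
  for (rep in 1:5) {
    orth <- function(k) {
      raw <- scale(matrix(rnorm(30 * k), 30, k), scale = FALSE)
      std(qr.Q(qr(raw)))
    }
    X <- orth(5); Y <- orth(2)    # orthogonal standardized columns
    fit <- fit_scca(X, Y, penalty_u = sqrt(5), penalty_v = sqrt(2))
    cc <- cancor(X, Y)$cor[1]
    expect_equal(abs(fit$canonical_correlation), cc, tolerance = 1e-4)
  }
})

test_that("canonical coefficients rank by magnitude and flag exclusions", {
  set.seed(66)
  X <- std(matrix(rnorm(60 * 8), 60, 8))
  colnames(X) <- paste0("m", 1:8)
  y <- rep(0:1, each = 30)
  X[, 3] <- std(X[, 3] + y * 2)
  fit <- fit_scca(X, group_indicator_matrix(y), penalty_u = 1.5)
  cc <- canonical_coefficients(fit)
  expect_equal(cc$ranked$abs_weight, sort(cc$ranked$abs_weight,
                                          decreasing = TRUE))
  expect_identical(cc$ranked$marker[1], "m3")
  expect_setequal(c(cc$ranked$marker, cc$excluded), paste0("m", 1:8))
  # ranking invariant to column order
  perm <- sample(8)
  fit2 <- fit_scca(X[, perm], group_indicator_matrix(y), penalty_u = 1.5)
  cc2 <- canonical_coefficients(fit2)
  expect_identical(cc$ranked$marker, cc2$ranked$marker)
})

test_that("discriminant ROC separates real structure and not permuted labels", {
  set.seed(67)
  n <- 72
  y <- rep(0:1, each = n / 2)
  X <- std(cbind(matrix(rnorm(n * 4), n, 4), sig = rnorm(n) + 3 * y))
  fit <- fit_scca(X, group_indicator_matrix(y))
  r <- scca_discriminant_roc(X, y, fit)
  expect_gt(r$auc, 0.9)
  yp <- sample(y)
  fitp <- fit_scca(X, group_indicator_matrix(yp))
  rp <- scca_discriminant_roc(X, yp, fitp)
  expect_lt(abs(rp$auc - 0.5), 0.2)
  expect_error(scca_discriminant_roc(X, rep(1, n), fit), "both classes")
})

test_that("resubstitution is optimistic relative to leave-one-out", {
  set.seed(68)
  diffs <- vapply(1:5, function(rep) {
    n <- 30
    y <- rep(0:1, each = n / 2)
    X <- std(cbind(matrix(rnorm(n * 5), n, 5), rnorm(n) + 0.8 * y))
    fit <- fit_scca(X, group_indicator_matrix(y))
    resub <- scca_discriminant_roc(X, y, fit, mode = "resubstitution")$auc
    loo <- scca_discriminant_roc(X, y, fit, mode = "loo_cv")$auc
    resub - loo
  }, 1.0)
  expect_gt(mean(diffs), 0)
})

test_that("vector projection yields coordinates, marker vectors and degeneracy flags", {
  set.seed(69)
  n <- 40
  y <- rep(0:1, each = n / 2)
  X <- std(matrix(rnorm(n * 5), n, 5))
  colnames(X) <- paste0("m", 1:5)
  Y <- group_indicator_matrix(y)
  fit <- fit_scca(X, Y, penalty_u = sqrt(5))
  pr <- vector_projection(fit, X, Y)
  # binary outcome: cross-product has rank 1, second pair is degenerate
  expect_true(pr$degenerate)
  expect_equal(unname(pr$coordinates[, 1]), unname(fit$scores))
  # a marker identical to variate 1 has direction (+/-1, 0): with
  # penalty 1 the fit picks the single most informative marker, so its
  # scores coincide with that marker's column
  Xs <- std(cbind(m1 = rnorm(n) + 2 * y, m2 = rnorm(n), m3 = rnorm(n)))
  fit2 <- fit_scca(Xs, Y, penalty_u = 1)
  pr2 <- vector_projection(fit2, Xs, Y)
  picked <- names(which(fit2$u != 0))
  expect_equal(abs(pr2$marker_vectors[picked, "cv1"]), 1,
               tolerance = 1e-9, ignore_attr = TRUE)
  # a two-dimensional continuous outcome supports a second pair
  Yc <- std(matrix(rnorm(n * 2), n, 2))
  fit3 <- fit_scca(X, Yc, penalty_u = sqrt(5), penalty_v = sqrt(2))
  pr3 <- vector_projection(fit3, X, Yc)
  expect_false(pr3$degenerate)
  expect_identical(pr3$coordinates,
                   vector_projection(fit3, X, Yc)$coordinates)
})

test_that("degenerate input is flagged instead of fabricating weights", {
  X <- matrix(0, 10, 3)
  Y <- group_indicator_matrix(rep(0:1, each = 5))
  fit <- fit_scca(X, Y)
  expect_true(all(fit$u == 0))
  expect_true(canonical_coefficients(fit)$degenerate)
})
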