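test_that("Mann-Whitney matches hand-derived and enumerated exact p-values", {
  # fully separated: U = 0, two-sided p = 2 / choose(6,3) = 0.1
  t1 <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t1$statistic, 0)
  expect_equal(t1$p_raw, 0.1)
  expect_true(t1$exact)
  # identical multisets: p = 1
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_raw, 1)
  # exact branch agrees with a full enumeration oracle on random samples
  set.seed(41)
  for (rep in 1:20) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- round(rnorm(nx), 6); y <- round(rnorm(ny), 6)
    if (nx + ny > 12) next
    expect_equal(mann_whitney(x, y)$p_raw, mw_exact_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("approximate Mann-Whitney p stays close to the exact p for small samples", {
  set.seed(42)
  for (rep in 1:25) {
    x <- rnorm(5); y <- rnorm(6)
    p_exact <- mann_whitney(x, y)$p_raw
    p_approx <- mann_whitney(x, y, exact_max = 0L)$p_raw
    expect_lt(abs(p_exact - p_approx), 0.03)
  }
})

test_that("Mann-Whitney is invariant under strictly monotone transforms", {
  set.seed(7)
  x <- rlnorm(15); y <- rlnorm(20) * 1.5
  p0 <- mann_whitney(x, y)$p_raw
  expect_identical(mann_whitney(log(x), log(y))$p_raw, p0)
  expect_identical(mann_whitney(x^3, y^3)$p_raw, p0)
})

test_that("the U statistic carries the empirical-AUC identity", {
  set.seed(8)
  for (rep in 1:25) {
    x <- rnorm(7); y <- rnorm(9) + 0.5
    u_x <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    auc <- roc_curve(c(x, y), c(rep(0, 7), rep(1, 9)))$auc
    # AUC of y over x = U_y / (nx ny) = 1 - U_x / (nx ny)
    expect_equal(auc, 1 - u_x / (7 * 9), tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis with Dunn post-hoc behaves across group structures", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  res <- kruskal_wallis_dunn(same)
  expect_lt(res$kw$statistic, 1e-9)
  expect_true(all(res$pairwise$p_adjusted > 0.99))

  far <- kruskal_wallis_dunn(list(a = c(1, 2), b = c(3, 4),
                                  c = c(100, 101)))
  extreme <- far$pairwise$p_raw[far$pairwise$group_a == "a" &
                                  far$pairwise$group_b == "c"]
  expect_equal(min(far$pairwise$p_raw), extreme)
  expect_error(kruskal_wallis_dunn(list(1:3, 4:6)), "mann_whitney")
})

test_that("Kruskal-Wallis chi-square p is close to the full permutation p", {
  # tie-free H from the rank-sum formula (independent of kruskal.test)
  h_of <- function(vals, sizes) {
    g <- rep(seq_along(sizes), sizes)
    r <- rank(vals)
    n <- length(vals)
    12 / (n * (n + 1)) *
      sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  }
  perm_p <- function(groups) {
    pooled <- unlist(groups)
    sizes <- lengths(groups)
    h_obs <- h_of(pooled, sizes)
    n <- length(pooled)
    count <- 0; total <- 0
    for (c1 in asplit(combn(n, sizes[1]), 2)) {
      rest <- setdiff(seq_len(n), c1)
      for (c2 in asplit(combn(length(rest), sizes[2]), 2)) {
        idx <- c(c1, rest[c2], setdiff(rest, rest[c2]))
        count <- count + (h_of(pooled[idx], sizes) >= h_obs - 1e-9)
        total <- total + 1
      }
    }
    count / total
  }
  set.seed(9)
  diffs <- vapply(1:60, function(rep) {
    groups <- list(rnorm(3), rnorm(3) + 0.5, rnorm(3) + 1)
    abs(kruskal_wallis_dunn(groups)$kw$p_raw - perm_p(groups))
  }, 1.0)
  # at the smallest usable group sizes the chi-square approximation sits
  # right at its accuracy limit; require the mean discrepancy to stay at
  # 0.05 up to Monte-Carlo error of this check, and no gross outliers
  expect_lte(mean(diffs), 0.05 + 2 * sd(diffs) / sqrt(length(diffs)))
  expect_lt(max(diffs), 0.15)
})

test_that("the trend test reports direction, antisymmetry and calibrated p", {
  up <- cuzick_trend(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_gt(up$statistic, 0)
  down <- cuzick_trend(rev(list(c(1, 2), c(3, 4), c(5, 6))))
  expect_equal(down$statistic, -up$statistic)
  expect_equal(cuzick_trend(list(c(2, 2), c(2, 2), c(2, 2)))$statistic, 0)
  expect_equal(cuzick_trend(list(c(2, 2), c(2, 2), c(2, 2)))$p_raw, 1)

  # Monte-Carlo permutation oracle
  set.seed(10)
  groups <- list(rnorm(4), rnorm(4) + 0.4, rnorm(4) + 0.7)
  res <- cuzick_trend(groups)
  pooled <- unlist(groups)
  l <- rep(0:2, each = 4)
  t_obs <- sum(l * rank(pooled))
  et <- mean(rank(pooled)) * sum(l)
  perm_t <- replicate(1e5, sum(l * sample(rank(pooled))))
  p_mc <- mean(abs(perm_t - et) >= abs(t_obs - et) - 1e-9)
  expect_lt(abs(res$p_raw - p_mc), 0.02)
})

test_that("chi-square matches the 2x2 closed form and rejects zero margins", {
  expect_equal(chi_square(matrix(c(10, 0, 0, 10), 2))$statistic, 20)
  t2 <- chi_square(matrix(c(5, 5, 5, 5), 2))
  expect_equal(t2$statistic, 0)
  expect_equal(t2$p_raw, 1)
  expect_equal(chi_square(matrix(c(18, 18, 18, 18), 2))$statistic, 0)
  set.seed(11)
  for (rep in 1:10) {
    tab <- matrix(sample(1:30, 4), 2)
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    n <- sum(tab)
    closed <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(chi_square(tab)$statistic, closed, tolerance = 1e-12)
  }
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})

test_that("Holm adjustment matches the hand example and a brute-force oracle", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(12)
  for (rep in 1:1000) {
    p <- runif(sample(1:12, 1))
    expect_equal(holm_adjust(p), holm_oracle(p), tolerance = 1e-12)
  }
})

test_that("fold differences are median ratios with Holm-flagged significance", {
  m <- cbind(M1 = c(10, 10, 12, 20, 20, 22), M2 = c(5, 6, 7, 5, 6, 7))
  panel <- panel_from_matrix(m, steatosis = c(0, 0, 0, 1, 1, 1))
  fd <- fold_differences(panel)
  expect_equal(fd$fold[fd$marker == "M1"], 2)
  expect_equal(fd$log2_fold[fd$marker == "M1"], 1)
  expect_equal(fd$fold[fd$marker == "M2"], 1)
  expect_false(any(fd$significant[fd$marker == "M2"]))
  expect_true(all(fd$p_adjusted >= fd$p_raw))
  # fold equals 10^(difference of median log10 values)
  expect_equal(fd$fold,
               10^(apply(log10(m[4:6, ]), 2, median) -
                     apply(log10(m[1:3, ]), 2, median)),
               ignore_attr = TRUE, tolerance = 1e-9)
})
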