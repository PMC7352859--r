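test_that("Spearman matrix handles perfect, exact and tied cases", {
  v <- cbind(a = c(1, 2, 3), b = c(3, 2, 1))
  sm <- spearman_matrix(v, min_pairs = 3L)
  expect_equal(sm$rho["a", "b"], -1)

  # n = 4 perfectly monotone: exact two-sided p = 2/24
  v4 <- cbind(a = c(1, 2, 3, 4), b = c(2, 5, 7, 11))
  sm4 <- spearman_matrix(v4)
  expect_equal(sm4$rho["a", "b"], 1)
  expect_equal(sm4$p["a", "b"], 2 / 24, tolerance = 1e-12)

  # invariance under strictly monotone transforms
  set.seed(31)
  x <- rlnorm(20); y <- x + rlnorm(20)
  s1 <- spearman_matrix(cbind(x, y))
  s2 <- spearman_matrix(cbind(log(x), sqrt(y)))
  expect_equal(s1$rho, s2$rho, ignore_attr = TRUE)
  expect_equal(s1$p, s2$p, ignore_attr = TRUE)
})

test_that("pairwise-complete handling marks sparse pairs unavailable", {
  v <- cbind(a = c(1, 2, 3, 4, NA, 6), b = c(2, 1, NA, 5, 6, 7),
             c = c(NA, NA, NA, 1, 2, 3))
  sm <- spearman_matrix(v, min_pairs = 4L)
  expect_false(is.na(sm$rho["a", "b"]))       # 4 complete pairs
  expect_true(is.na(sm$rho["a", "c"]))        # only 2 complete pairs
  expect_identical(sm$n["a", "c"], 2L)
})

test_that("network edges follow the p < alpha rule with correct degrees", {
  set.seed(32)
  base <- rnorm(30)
  m <- cbind(A = base + rnorm(30, sd = 1e-3),
             B = base + rnorm(30, sd = 1e-3),
             C = rnorm(30))
  panel <- panel_from_matrix(10^m, steatosis = rep(0L, 30))
  net <- build_network(panel, group = "ctrl")
  ab <- net$edges$marker_a == "A" & net$edges$marker_b == "B"
  expect_true(any(ab))
  expect_equal(net$edges$sign[ab], "+")
  # handshake lemma
  expect_equal(sum(net$degrees), 2L * nrow(net$edges))
  # alpha = 0 -> empty network
  empty <- build_network(panel, alpha = 0)
  expect_identical(nrow(empty$edges), 0L)
  expect_true(all(empty$degrees == 0L))
  expect_error(build_network(panel[1:4, ]), ">= 5 samples")
})

test_that("the duplicated-marker edge is recovered in nearly all cohorts", {
  hits <- 0
  for (s in 1:40) {
    set.seed(600 + s)
    base <- rnorm(30)
    m <- cbind(A = base + rnorm(30, sd = 1e-2),
               B = base + rnorm(30, sd = 1e-2),
               C = rnorm(30))
    panel <- panel_from_matrix(10^m, steatosis = rep(0L, 30))
    net <- build_network(panel)
    hits <- hits + any(net$edges$marker_a == "A" & net$edges$marker_b == "B")
  }
  expect_gte(hits / 40, 0.95)
})

test_that("a marker coupled negatively to others yields only negative strong edges", {
  p <- 6L
  R <- diag(p)
  R[1, 2:5] <- R[2:5, 1] <- -0.6
  R[2:5, 2:5][upper.tri(matrix(0, 4, 4))] <- 0.35
  R[2:5, 2:5][lower.tri(matrix(0, 4, 4))] <- 0.35
  diag(R) <- 1
  cfg <- cohort_config(n_control = 0L, n_case = 36L, grade_split = c(18L, 18L),
                       marker_names = c("fT4", paste0("M", 2:6)),
                       log10_means_control = rep(1, p),
                       log10_sds = rep(0.2, p),
                       corr_case = R, repair_psd = TRUE)
  panel <- generate_cohort(cfg, seed = 33)
  net <- build_network(panel, group = "case")
  ft4 <- net$edges[net$edges$marker_a == "fT4" | net$edges$marker_b == "fT4", ]
  strong <- ft4[abs(ft4$rho) > 0.35, ]
  expect_gte(nrow(strong), 3)
  expect_true(all(strong$sign == "-"))
})

test_that("bootstrap support is deterministic and high for real structure", {
  set.seed(34)
  base <- rnorm(30)
  m <- cbind(A = base + rnorm(30, sd = 1e-3),
             B = base + rnorm(30, sd = 1e-3),
             C = rnorm(30), D = rnorm(30))
  panel <- panel_from_matrix(10^m, steatosis = rep(0L, 30))
  n1 <- bootstrap_network(panel, n_boot = 40, seed = 5)
  n2 <- bootstrap_network(panel, n_boot = 40, seed = 5)
  expect_identical(n1$edges, n2$edges)
  ab <- n1$edges$marker_a == "A" & n1$edges$marker_b == "B"
  expect_equal(n1$edges$boot_support[ab], 1)
  expect_error(bootstrap_network(panel, n_boot = 0), "n_boot")

  # spurious edges among independent markers have weak support
  set.seed(35)
  ind <- panel_from_matrix(10^matrix(rnorm(30 * 8), 30, 8),
                           steatosis = rep(0L, 30))
  nb <- bootstrap_network(ind, n_boot = 60, seed = 6)
  if (nrow(nb$edges)) expect_lt(mean(nb$edges$boot_support), 0.6)
})

test_that("node-degree tables aggregate consistently across groups", {
  set.seed(36)
  m <- 10^matrix(rnorm(40 * 5), 40, 5)
  colnames(m) <- paste0("M", 1:5)
  pa <- panel_from_matrix(m[1:20, ], steatosis = rep(0L, 20))
  pb <- panel_from_matrix(m[21:40, ], steatosis = rep(0L, 20))
  na_ <- build_network(pa, group = "control")
  nb_ <- build_network(pb, group = "case")
  nd <- node_degree_table(list(na_, nb_))
  expect_identical(colnames(nd$degrees), c("control", "case"))
  expect_equal(colSums(nd$degrees), 2 * nd$totals$n_edges,
               ignore_attr = TRUE)
  expect_equal(nd$totals$n_edges,
               nd$totals$n_positive + nd$totals$n_negative)
  nc_ <- build_network(panel_from_matrix(m[1:20, 1:4], rep(0L, 20)))
  expect_error(node_degree_table(list(na_, nc_)), "node set")
})

test_that("case networks under the study configuration are denser than control", {
  cfg <- default_study_config()
  denser <- 0
  for (s in 1:15) {
    panel <- generate_cohort(cfg, seed = 700 + s)
    nc <- build_network(panel[panel$steatosis == 0, ], group = "control")
    nk <- build_network(panel[panel$steatosis == 1, ], group = "case")
    denser <- denser + (nrow(nk$edges) > nrow(nc$edges))
  }
  expect_gte(denser / 15, 0.8)
})

test_that("networks export as GraphML importable by igraph", {
  set.seed(37)
  panel <- panel_from_matrix(10^matrix(rnorm(30 * 4), 30, 4),
                             steatosis = rep(0L, 30))
  net <- build_network(panel)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(as.integer(igraph::vcount(g)), length(net$nodes))
  expect_equal(as.integer(igraph::ecount(g)), nrow(net$edges))
})
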