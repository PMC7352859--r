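# Nonparametric univariate comparisons, trend tests, multiplicity control ----

#' Mann-Whitney U test (two-sided)
#'
#' Exact p by enumeration (via the null U distribution) when the pooled
#' sample has at most 12 tie-free observations; otherwise the normal
#' approximation with tie correction and, by default, continuity
#' correction. The reported statistic is min(U_x, U_y).
#'
#' @param x,y numeric samples (non-empty).
#' @param continuity apply the continuity correction in the normal
#'   approximation (ignored in the exact branch).
#' @param exact_max use the exact distribution when `length(x) + length(y)`
#'   is at most this and the pooled data are tie-free.
#' @return list of class `bp_test`: `marker` (NA here), `method`,
#'   `statistic` (min U), `p_raw`, `group_medians` (with IQRs), `exact`.
#' @export
mann_whitney <- function(x, y, continuity = TRUE, exact_max = 12L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty",
                                     call. = FALSE)
  nx <- length(x); ny <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (nx + ny) <= exact_max && !ties
  ht <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided", exact = use_exact,
    correct = continuity))
  ux <- unname(ht$statistic)          # U for x (rank-sum form)
  u <- min(ux, nx * ny - ux)
  .bp_test(method = "mann_whitney", statistic = u,
           p_raw = min(1, unname(ht$p.value)),
           group_medians = list(x = .med_iqr(x), y = .med_iqr(y)),
           exact = use_exact)
}

.med_iqr <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
  c(median = q[2], q25 = q[1], q75 = q[3])
}

.bp_test <- function(method, statistic, p_raw, p_adjusted = NA_real_, ...) {
  structure(list(method = method, statistic = unname(statistic),
                 p_raw = unname(p_raw), p_adjusted = p_adjusted, ...),
            class = "bp_test")
}

#' Kruskal-Wallis test with Dunn's pairwise post-hoc comparisons
#'
#' Kruskal-Wallis H with tie correction; Dunn z statistics on the pooled
#' mid-ranks for every group pair, adjusted across the pairwise family
#' (Holm by default).
#'
#' @param groups list of >= 3 non-empty numeric vectors, in clinical order.
#' @param p_adjust adjustment for the Dunn family: "holm", "bonferroni" or
#'   "none".
#' @return list with `kw` (a `bp_test` for the omnibus H) and `pairwise`
#'   (data.frame: group_a, group_b, z, p_raw, p_adjusted).
#' @export
kruskal_wallis_dunn <- function(groups, p_adjust = c("holm", "bonferroni",
                                                     "none")) {
  p_adjust <- match.arg(p_adjust)
  if (length(groups) < 3L)
    stop("need >= 3 groups; use mann_whitney() for two", call. = FALSE)
  if (any(!vapply(groups, length, 1L)))
    stop("every group must be non-empty", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  kw <- stats::kruskal.test(groups)
  pooled <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(pooled)
  N <- length(pooled)
  rbar <- tapply(r, g, mean)
  n <- lengths(groups)
  tie_counts <- table(pooled)
  tie_term <- sum(tie_counts^3 - tie_counts) / (12 * (N - 1))
  pairs <- utils::combn(length(groups), 2)
  z <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[i] + 1 / n[j]))
    (rbar[i] - rbar[j]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  pw <- data.frame(group_a = names(groups)[pairs[1, ]],
                   group_b = names(groups)[pairs[2, ]],
                   z = as.numeric(z), p_raw = as.numeric(p),
                   p_adjusted = stats::p.adjust(p, method = if (p_adjust == "none") "none" else p_adjust),
                   stringsAsFactors = FALSE)
  list(kw = .bp_test(method = "kruskal_wallis",
                     statistic = unname(kw$statistic),
                     p_raw = unname(kw$p.value),
                     df = unname(kw$parameter)),
       pairwise = pw)
}

#' Nonparametric test for linear trend across ordered groups (Cuzick)
#'
#' Wilcoxon-type trend statistic: T = sum of group score times pooled
#' mid-rank, standardized under the permutation null (the mid-rank variance
#' handles ties). Positive z means the outcome increases with the score.
#'
#' @param groups list of >= 3 numeric vectors in the group order.
#' @param scores ordinal score per group (default 0, 1, 2, ...).
#' @return a `bp_test` with `statistic` = z.
#' @export
cuzick_trend <- function(groups, scores = seq_along(groups) - 1) {
  if (length(groups) < 3L) stop("need >= 3 ordered groups", call. = FALSE)
  stopifnot(length(scores) == length(groups))
  pooled <- unlist(groups, use.names = FALSE)
  n <- lengths(groups)
  N <- length(pooled)
  l <- rep(scores, n)
  r <- rank(pooled)
  T_obs <- sum(l * r)
  L <- sum(scores * n)
  ET <- mean(r) * L
  var_r <- sum((r - mean(r))^2) / (N - 1)
  VT <- sum((l - L / N)^2) * var_r
  if (VT <= 0) {
    z <- 0; p <- 1
  } else {
    z <- (T_obs - ET) / sqrt(VT)
    p <- 2 * stats::pnorm(-abs(z))
  }
  .bp_test(method = "cuzick_trend", statistic = z, p_raw = p,
           T = T_obs, expected = ET, variance = VT)
}

#' Pearson chi-square test on a 2 x k count table
#'
#' No continuity correction (following the convention for comparing
#' percentage-type variables between clinical groups).
#'
#' @param table a 2 x k matrix of nonnegative integer counts.
#' @return a `bp_test` with `statistic` = X-squared, `df` = k - 1.
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin in the count table", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  .bp_test(method = "chi_square", statistic = unname(ht$statistic),
           p_raw = unname(ht$p.value), df = unname(ht$parameter))
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p_values probabilities in [0, 1].
#' @return adjusted p-values in the input order.
#' @export
holm_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "holm")
}

#' Per-marker fold differences between cases and controls
#'
#' Fold = case median / control median on the native concentration scale
#' (equivalently 10^ of the difference of median log10 values). The
#' significance flag comes from Holm-adjusted Mann-Whitney p-values over
#' the full marker family.
#'
#' @param panel a biomarker panel with both groups present.
#' @param alpha familywise significance level for the flag.
#' @return data.frame: marker, fold, log2_fold, median_control, median_case,
#'   p_raw, p_adjusted, significant.
#' @export
fold_differences <- function(panel, alpha = 0.05) {
  validate_panel(panel)
  mm <- marker_matrix(panel)
  is_case <- panel$steatosis == 1L
  if (!any(is_case) || !all(is_case == (panel$steatosis == 1L)) ||
      !any(!is_case))
    stop("both clinical groups must be non-empty", call. = FALSE)
  res <- lapply(colnames(mm), function(m) {
    x <- mm[is_case, m]; y <- mm[!is_case, m]
    tt <- mann_whitney(x, y)
    data.frame(marker = m,
               median_case = stats::median(x, na.rm = TRUE),
               median_control = stats::median(y, na.rm = TRUE),
               p_raw = tt$p_raw, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$fold <- res$median_case / res$median_control
  res$log2_fold <- log2(res$fold)
  res$p_adjusted <- holm_adjust(res$p_raw)
  res$significant <- res$p_adjusted < alpha
  res[, c("marker", "fold", "log2_fold", "median_control", "median_case",
          "p_raw", "p_adjusted", "significant")]
}

#' Tidy univariate comparison table for every marker
#'
#' Mann-Whitney case vs control per marker with group medians/IQRs, fold
#' differences, and Holm adjustment over the marker family.
#'
#' @param panel a biomarker panel.
#' @param alpha familywise level.
#' @return data.frame, one row per marker.
#' @export
univariate_table <- function(panel, alpha = 0.05) {
  fd <- fold_differences(panel, alpha = alpha)
  mm <- marker_matrix(panel)
  is_case <- panel$steatosis == 1L
  iqr <- t(vapply(fd$marker, function(m) {
    c(.med_iqr(mm[!is_case, m]), .med_iqr(mm[is_case, m]))
  }, numeric(6)))
  colnames(iqr) <- c("control_median", "control_q25", "control_q75",
                     "case_median", "case_q25", "case_q75")
  cbind(fd[, c("marker", "fold", "log2_fold", "p_raw", "p_adjusted",
               "significant")],
        as.data.frame(iqr))
}
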