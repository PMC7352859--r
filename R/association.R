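# Univariate screening, logistic regression, ROC ------------------------------

#' Univariate screening for multivariable model entry
#'
#' Continuous variables (markers, age, BMI z, waist) get a Mann-Whitney
#' case-vs-control p; categorical ones (sex) a chi-square p. Variables with
#' p below `alpha_entry` are selected; the forced adjustment covariates are
#' always retained regardless of their p.
#'
#' @param panel a biomarker panel.
#' @param alpha_entry entry threshold (default 0.2, the methods-section
#'   rule; the forest-figure caption's 0.05 is available by setting it).
#' @param forced covariates always kept (default sex, age, bmi_z, waist).
#' @return data.frame: variable, type, p_raw, selected, forced.
#' @export
univariate_screen <- function(panel, alpha_entry = 0.2,
                              forced = c("sex", "age", "bmi_z", "waist")) {
  validate_panel(panel)
  y <- panel$steatosis
  if (length(unique(y)) < 2L) stop("outcome must have both classes",
                                   call. = FALSE)
  vars <- c(panel_markers(panel),
            intersect(c("sex", "age", "bmi_z", "waist"), names(panel)))
  rows <- lapply(vars, function(v) {
    vals <- panel[[v]]
    if (v == "sex") {
      tab <- table(factor(y, levels = 0:1), factor(vals))
      p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1
           else chi_square(tab)$p_raw
      type <- "categorical"
    } else {
      p <- mann_whitney(vals[y == 1], vals[y == 0])$p_raw
      type <- "continuous"
    }
    data.frame(variable = v, type = type, p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$forced <- out$variable %in% forced
  out$selected <- out$p_raw < alpha_entry | out$forced
  out
}

#' Multivariable logistic regression with odds ratios
#'
#' Maximum-likelihood fit (IRLS via `glm`). Continuous markers should be
#' entered on the log10 scale so coefficients read as per-1-log changes;
#' [logistic_design()] does this. Wald standard errors; OR = exp(coef)
#' with 95% CI exp(coef +/- 1.96 se). Quasi-complete separation is
#' detected (fitted probabilities collapsing to 0/1 or runaway
#' coefficients) and flagged rather than silently reported.
#'
#' @param design data.frame of predictors (numeric columns).
#' @param outcome binary 0/1 vector.
#' @return object of class `logistic_model`: `terms` data.frame (term,
#'   coefficient, se, odds_ratio, ci_low, ci_high, p), `log_likelihood`,
#'   `null_log_likelihood`, `n`, `converged`, `separation`.
#' @export
fit_logistic <- function(design, outcome) {
  design <- as.data.frame(design, check.names = FALSE)
  outcome <- as.integer(outcome)
  stopifnot(nrow(design) == length(outcome))
  if (nrow(design) <= ncol(design) + 1L)
    stop("more terms than samples support", call. = FALSE)
  const <- vapply(design, function(v) stats::sd(v) == 0, TRUE)
  if (any(const))
    stop(sprintf("constant column(s) in design: %s",
                 paste(names(design)[const], collapse = ", ")), call. = FALSE)
  X <- as.matrix(design)
  qr_rank <- qr(cbind(1, X))$rank
  if (qr_rank < ncol(X) + 1L) {
    drop_idx <- qr(cbind(1, X))$pivot[-seq_len(qr_rank)] - 1L
    stop(sprintf("singular design; collinear term(s): %s",
                 paste(colnames(X)[drop_idx[drop_idx > 0]], collapse = ", ")),
         call. = FALSE)
  }
  dat <- data.frame(.y = outcome, design, check.names = FALSE)
  form <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`",
                                                        names(design)),
                                                collapse = " + ")))
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(),
                                     data = dat))
  co <- summary(fit)$coefficients
  eps <- 1e-8
  separation <- any(fit$fitted.values < eps | fit$fitted.values > 1 - eps) ||
    any(abs(stats::coef(fit)[-1]) > 15)
  if (separation)
    warning("possible (quasi-)separation: odds ratios may be unbounded",
            call. = FALSE)
  terms <- data.frame(
    term = gsub("^`|`$", "", rownames(co)),
    coefficient = co[, 1], se = co[, 2],
    odds_ratio = exp(co[, 1]),
    ci_low = exp(co[, 1] - 1.96 * co[, 2]),
    ci_high = exp(co[, 1] + 1.96 * co[, 2]),
    p = co[, 4], stringsAsFactors = FALSE)
  rownames(terms) <- NULL
  null_ll <- -0.5 * fit$null.deviance
  structure(list(terms = terms,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 null_log_likelihood = as.numeric(stats::logLik(
                   stats::update(fit, . ~ 1))),
                 n = nrow(design),
                 converged = fit$converged,
                 separation = separation,
                 fit = fit),
            class = "logistic_model")
}

#' Build a logistic design matrix from a panel
#'
#' Selected markers enter as log10 concentrations (coefficients per 1-log
#' change); covariates enter on their native scale.
#'
#' @param panel a biomarker panel.
#' @param markers marker names to include (log10-transformed).
#' @param covariates covariate column names to include as-is.
#' @param log_markers log10-transform the markers (default TRUE).
#' @return data.frame of predictors; marker columns named
#'   `log10(<marker>)` when transformed.
#' @export
logistic_design <- function(panel, markers, covariates = c("sex", "age",
                                                           "bmi_z", "waist"),
                            log_markers = TRUE) {
  stopifnot(all(markers %in% panel_markers(panel)))
  covariates <- intersect(covariates, names(panel))
  out <- as.data.frame(panel, check.names = FALSE)[, covariates, drop = FALSE]
  for (m in markers) {
    v <- panel[[m]]
    out[[if (log_markers) sprintf("log10(%s)", m) else m]] <-
      if (log_markers) log10(v) else v
  }
  out
}

#' Empirical ROC curve with AUC, DeLong CI and Youden-optimal cutoff
#'
#' The curve sweeps every distinct score as a threshold (predict positive
#' when score > t). AUC is the trapezoidal area, which with mid-rank tie
#' handling equals the Mann-Whitney statistic U/(n1*n0). The 95% CI uses
#' DeLong's placement-value variance. The reported cutoff maximizes the
#' Youden index (sensitivity + specificity - 1); ties are broken toward
#' higher specificity (the larger threshold).
#'
#' @param scores numeric classifier scores (higher = more case-like).
#' @param labels binary labels, 1 = case.
#' @return object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `auc_ci`, `auc_se`, `youden_cutoff`,
#'   `sens_at_cutoff`, `spec_at_cutoff`, `degenerate`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present",
                                 call. = FALSE)
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  degenerate <- stats::sd(scores) == 0
  # thresholds: below min, each distinct score, i.e. predict positive if > t
  thr <- c(-Inf, sort(unique(scores)))
  sens <- vapply(thr, function(t) mean(pos > t), 1.0)
  spec <- vapply(thr, function(t) mean(neg <= t), 1.0)
  # DeLong placement values
  v10 <- vapply(pos, function(s) mean(s > neg) + 0.5 * mean(s == neg), 1.0)
  v01 <- vapply(neg, function(s) mean(pos > s) + 0.5 * mean(pos == s), 1.0)
  auc <- mean(v10)
  var_auc <- stats::var(v10) / n1 + stats::var(v01) / n0
  se <- sqrt(max(var_auc, 0))
  ci <- c(max(0, auc - 1.96 * se), min(1, auc + 1.96 * se))
  youden <- sens + spec - 1
  best <- which(youden == max(youden))
  best <- best[length(best)]       # largest threshold -> higher specificity
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, auc_ci = ci, auc_se = se,
                 youden_cutoff = thr[best],
                 sens_at_cutoff = sens[best], spec_at_cutoff = spec[best],
                 n_case = n1, n_control = n0,
                 degenerate = degenerate),
            class = "roc_result")
}

#' Single-marker ROC with the cutoff reported in native units
#'
#' Runs [roc_curve()] on log10 concentrations of one marker and converts
#' the Youden-optimal cutoff back to native units.
#'
#' @param panel a biomarker panel.
#' @param marker marker name.
#' @return an `roc_result` with `cutoff_native` added.
#' @export
marker_roc <- function(panel, marker) {
  stopifnot(marker %in% panel_markers(panel))
  r <- roc_curve(log10(panel[[marker]]), panel$steatosis)
  r$marker <- marker
  r$cutoff_native <- 10^r$youden_cutoff
  r
}
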