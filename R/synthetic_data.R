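# Synthetic cohort generation -------------------------------------------------
#
# Two-group (steatosis vs no-steatosis) biomarker panels are generated as
# multivariate log-normal draws: log10 concentrations are multivariate normal
# with per-marker means, a case-minus-control location shift, an additional
# shift per ultrasound severity grade, and a group-specific correlation
# matrix. Clinical covariates (sex, age, BMI-for-age z, waist) are drawn
# independently of the markers except for an optional linear coupling of the
# BMI z-score into selected markers on the log scale.

#' Reserved (non-marker) column names of a biomarker panel
#'
#' Every other column of a panel CSV is treated as a marker concentration.
#' @export
PANEL_RESERVED_COLUMNS <- c("sample_id", "steatosis", "grade",
                            "sex", "age", "bmi_z", "waist")

#' Construct a cohort configuration
#'
#' Bundles every parameter of the synthetic cohort generator and validates
#' the joint constraints (grade split, positive spreads, positive
#' semidefinite correlation matrices).
#'
#' @param n_control,n_case group sizes; defaults 36 + 36, the enrolled
#'   cohort size of the study design this generator emulates.
#' @param grade_split integer pair: cases with mild (grade 1) and with
#'   moderate/severe (grade 2) steatosis; must sum to `n_case`.
#' @param marker_names character vector of marker identifiers.
#' @param log10_means_control per-marker mean of log10 concentration in the
#'   control (no steatosis) group, in native units per marker.
#' @param log10_sds per-marker standard deviation of log10 concentration
#'   (shared between groups); all strictly positive.
#' @param effect_log10 per-marker case-minus-control shift on the log10
#'   scale (applied to every case).
#' @param grade_slope_log10 per-marker additional log10 shift per severity
#'   grade step (grade coded 0/1/2).
#' @param corr_control,corr_case marker correlation matrices per group;
#'   symmetric, unit diagonal, positive semidefinite.
#' @param covariate_params list controlling the clinical covariates; see
#'   [default_covariate_params()].
#' @param seed optional integer; stored and used by [generate_cohort()]
#'   when no explicit seed is passed there.
#' @param repair_psd if `TRUE`, correlation matrices that fail the positive
#'   semidefiniteness check are replaced by their nearest PSD projection
#'   (eigenvalue clipping) instead of being rejected. Off by default:
#'   invalid matrices are an error, never silently fixed.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 36L, n_case = 36L,
                          grade_split = c(18L, 18L),
                          marker_names,
                          log10_means_control,
                          log10_sds,
                          effect_log10 = rep(0, length(marker_names)),
                          grade_slope_log10 = rep(0, length(marker_names)),
                          corr_control = diag(length(marker_names)),
                          corr_case = corr_control,
                          covariate_params = default_covariate_params(),
                          seed = NULL,
                          repair_psd = FALSE) {
  p <- length(marker_names)
  stopifnot(is.character(marker_names), p >= 1L, !anyDuplicated(marker_names))
  n_control <- as.integer(n_control); n_case <- as.integer(n_case)
  grade_split <- as.integer(grade_split)
  if (length(grade_split) != 2L || any(grade_split < 0L))
    stop("`grade_split` must be two nonnegative counts (mild, moderate/severe)",
         call. = FALSE)
  if (sum(grade_split) != n_case)
    stop(sprintf("configuration error: grade_split (%d + %d) must sum to n_case (%d)",
                 grade_split[1], grade_split[2], n_case), call. = FALSE)
  for (nm in c("log10_means_control", "log10_sds", "effect_log10",
               "grade_slope_log10")) {
    v <- get(nm)
    if (length(v) != p)
      stop(sprintf("`%s` must have one entry per marker (%d)", nm, p),
           call. = FALSE)
  }
  if (any(log10_sds <= 0))
    stop("configuration error: all `log10_sds` must be > 0", call. = FALSE)
  corr_control <- .check_corr(corr_control, p, "corr_control", repair_psd)
  corr_case <- .check_corr(corr_case, p, "corr_case", repair_psd)
  structure(list(
    n_control = n_control, n_case = n_case, grade_split = grade_split,
    marker_names = marker_names,
    log10_means_control = stats::setNames(as.numeric(log10_means_control), marker_names),
    log10_sds = stats::setNames(as.numeric(log10_sds), marker_names),
    effect_log10 = stats::setNames(as.numeric(effect_log10), marker_names),
    grade_slope_log10 = stats::setNames(as.numeric(grade_slope_log10), marker_names),
    corr_control = corr_control, corr_case = corr_case,
    covariate_params = covariate_params, seed = seed
  ), class = "cohort_config")
}

.check_corr <- function(m, p, name, repair = FALSE) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(p, p)))
    stop(sprintf("configuration error: `%s` must be %d x %d", name, p, p),
         call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8)
    stop(sprintf("configuration error: `%s` is not symmetric", name),
         call. = FALSE)
  if (max(abs(diag(m) - 1)) > 1e-8)
    stop(sprintf("configuration error: `%s` must have unit diagonal", name),
         call. = FALSE)
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    if (!repair)
      stop(sprintf(
        "configuration error: `%s` is not positive semidefinite (min eigenvalue %.3g)",
        name, min(ev)), call. = FALSE)
    e <- eigen((m + t(m)) / 2, symmetric = TRUE)
    v <- pmax(e$values, 0)
    m <- e$vectors %*% (v * t(e$vectors))
    d <- sqrt(diag(m))
    m <- m / tcrossprod(d)
    diag(m) <- 1
  }
  dimnames(m) <- NULL
  m
}

#' Default clinical covariate distributions
#'
#' Age (years), sex (0/1 with equal probability in both groups), BMI-for-age
#' z-score and waist circumference (cm, linear in BMI z). Values chosen to
#' match an overweight adolescent cohort: control median age about 12,
#' case about 14; every participant above the +1 z overweight threshold;
#' cases heavier, with BMI increasing with steatosis grade. `coupling`
#' injects a fraction of the standardized BMI z into selected markers on
#' the log10 scale (producing marker-BMI Spearman correlations around
#' 0.2-0.35 at the default coefficient).
#' @export
default_covariate_params <- function() {
  list(
    age = list(control = c(mean = 12.5, sd = 2.2),
               case = c(mean = 14.0, sd = 2.0), range = c(10, 19)),
    sex = list(p_male = 0.5),
    bmi_z = list(control = c(mean = 2.2, sd = 0.7),
                 case = c(mean = 2.5, sd = 0.7),
                 grade_slope = 0.25, min = 1.05),
    waist = list(intercept = 62, slope = 9, sd = 5),
    coupling = list(markers = c("TGF-β", "ALT"), coef = 0.3)
  )
}

#' Generate a synthetic biomarker panel cohort
#'
#' Draws `n_control + n_case` participants. For each sample, log10 marker
#' concentrations are multivariate normal with mean
#' `log10_means_control + steatosis * effect_log10 + grade * grade_slope_log10`,
#' per-marker sd `log10_sds`, and the group's correlation matrix;
#' concentrations are `10^` of the draw, hence strictly positive.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; defaults to `config$seed`. The same config and
#'   seed always reproduce the identical panel.
#' @return a `data.frame` of class `biomarker_panel` with the reserved
#'   clinical columns followed by one column per marker.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- length(config$marker_names)
  n0 <- config$n_control; n1 <- config$n_case; n <- n0 + n1
  steatosis <- c(rep(0L, n0), rep(1L, n1))
  grade <- c(rep(0L, n0),
             rep(1L, config$grade_split[1]), rep(2L, config$grade_split[2]))

  cp <- config$covariate_params
  age <- numeric(n); bmi_z <- numeric(n)
  for (g in 0:1) {
    idx <- steatosis == g
    a <- if (g == 0) cp$age$control else cp$age$case
    age[idx] <- .rnorm_trunc(sum(idx), a["mean"], a["sd"], cp$age$range)
    b <- if (g == 0) cp$bmi_z$control else cp$bmi_z$case
    bmi_z[idx] <- stats::rnorm(sum(idx), b["mean"], b["sd"])
  }
  bmi_z <- bmi_z + cp$bmi_z$grade_slope * grade
  bmi_z <- pmax(bmi_z, cp$bmi_z$min)
  sex <- stats::rbinom(n, 1L, cp$sex$p_male)
  waist <- cp$waist$intercept + cp$waist$slope * bmi_z +
    stats::rnorm(n, 0, cp$waist$sd)

  # marker draws: one Cholesky factor per group, shared standard normals layout
  z <- matrix(stats::rnorm(n * p), n, p)
  log10x <- matrix(NA_real_, n, p)
  for (g in 0:1) {
    idx <- steatosis == g
    R <- if (g == 0) config$corr_control else config$corr_case
    L <- chol(R + diag(1e-10, p))
    log10x[idx, ] <- z[idx, , drop = FALSE] %*% L
  }
  log10x <- sweep(log10x, 2, config$log10_sds, `*`)
  mu <- outer(rep(1, n), config$log10_means_control) +
    outer(steatosis, config$effect_log10) +
    outer(as.numeric(grade), config$grade_slope_log10)
  log10x <- log10x + mu

  # optional BMI-z coupling on the log scale (adds coef * sd * standardized bmi)
  if (length(cp$coupling$markers) && cp$coupling$coef != 0) {
    zb <- (bmi_z - mean(bmi_z)) / stats::sd(bmi_z)
    for (m in intersect(cp$coupling$markers, config$marker_names)) {
      j <- match(m, config$marker_names)
      log10x[, j] <- log10x[, j] + cp$coupling$coef * config$log10_sds[j] * zb
    }
  }

  panel <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    steatosis = steatosis, grade = grade, sex = sex,
    age = age, bmi_z = bmi_z, waist = waist,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  markers <- as.data.frame(10^log10x)
  names(markers) <- config$marker_names
  panel <- cbind(panel, markers)
  class(panel) <- c("biomarker_panel", "data.frame")
  validate_panel(panel)
  panel
}

.rnorm_trunc <- function(n, mean, sd, range) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < range[1] | x > range[2]
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < range[1] | x > range[2]
  }
  x
}

#' Default study configuration: a 25-marker overweight adolescent cohort
#'
#' Encodes the study conditions the package's analyses assume: 36 controls
#' and 36 steatosis cases (18 mild, 18 moderate/severe), the 25 routinely
#' assayed biochemical, hematological and immunological markers, log-normal
#' marginals at physiological medians, case elevations concentrated in ALT,
#' GGT and TGF-β (with smaller shifts across the metabolic profile:
#' triglycerides, AST, insulin, HOMA-IR, CRP, ferritin, creatinine,
#' hemoglobin/hematocrit up; HO-1, alkaline phosphatase, HDL-c, vitamin D
#' down), monotone severity-grade slopes for ALT and triglycerides, and a
#' denser case-group correlation structure in which free thyroxine couples
#' negatively to the metabolic axis.
#'
#' @param seed optional integer stored in the config.
#' @return a [cohort_config()].
#' @export
default_study_config <- function(seed = NULL) {
  mk <- .default_marker_table()
  cohort_config(
    n_control = 36L, n_case = 36L, grade_split = c(18L, 18L),
    marker_names = mk$name,
    log10_means_control = mk$mean,
    log10_sds = mk$sd,
    effect_log10 = mk$effect,
    grade_slope_log10 = mk$slope,
    corr_control = .default_corr("control"),
    corr_case = .default_corr("case"),
    covariate_params = default_covariate_params(),
    seed = seed
  )
}

# name, control log10 mean (native units), log10 sd, case shift, grade slope
.default_marker_table <- function() {
  tab <- rbind(
    c("Glucose",               1.95, 0.05,  0.015, 0),
    c("Insulin",               1.18, 0.25,  0.120, 0),
    c("HOMA-IR",               0.52, 0.28,  0.140, 0),
    c("Total cholesterol",     2.20, 0.08,  0.008, 0),
    c("LDL-c",                 1.98, 0.10,  0.040, 0),
    c("HDL-c",                 1.65, 0.08, -0.030, -0.012),
    c("Triglycerides",         2.00, 0.15,  0.075, 0.030),
    c("Urea",                  1.45, 0.10, -0.020, 0),
    c("Creatinine",           -0.22, 0.08,  0.040, 0),
    c("us-CRP",                0.18, 0.45,  0.180, 0),
    c("AST",                   1.34, 0.12,  0.060, 0),
    c("ALT",                   1.26, 0.15,  0.180, 0.100),
    c("GGT",                   1.26, 0.12,  0.130, 0),
    c("Alkaline phosphatase",  2.30, 0.15, -0.070, -0.030),
    c("Total bilirubin",      -0.30, 0.20,  0.000, 0),
    c("Direct bilirubin",     -0.82, 0.20,  0.000, 0),
    c("Albumin",               0.64, 0.03,  0.003, 0),
    c("Vitamin D",             1.40, 0.15, -0.045, 0),
    c("fT4",                   0.08, 0.06, -0.012, 0),
    c("TSH",                   0.30, 0.25,  0.000, 0),
    c("Ferritin",              1.78, 0.30,  0.120, 0),
    c("Hemoglobin",            1.13, 0.04,  0.016, 0.006),
    c("Hematocrit",            1.60, 0.04,  0.016, 0.006),
    c("HO-1",                  0.40, 0.25, -0.120, 0),
    c("TGF-β",            1.40, 0.20,  0.270, 0)
  )
  data.frame(name = tab[, 1],
             mean = as.numeric(tab[, 2]), sd = as.numeric(tab[, 3]),
             effect = as.numeric(tab[, 4]), slope = as.numeric(tab[, 5]),
             stringsAsFactors = FALSE)
}

# Factor-model correlation matrices (guaranteed PSD): corr = BB' + diag resid.
# Latent axes: metabolic/adiposity, liver, hematologic, lipid, insulin,
# bilirubin, thyroid. The case matrix adds liver-metabolic cross loadings and
# a negative fT4 coupling to the metabolic axis, yielding a denser network.
.default_corr <- function(group = c("control", "case")) {
  group <- match.arg(group)
  mk <- .default_marker_table()$name
  p <- length(mk)
  B <- matrix(0, p, 7, dimnames = list(mk, c("met", "liv", "hem", "lip",
                                             "ins", "bil", "thy")))
  ld <- function(marker, axis, value) B[marker, axis] <<- value
  ld("Glucose", "met", 0.45); ld("Insulin", "met", 0.45)
  ld("HOMA-IR", "met", 0.45); ld("Triglycerides", "met", 0.35)
  ld("HDL-c", "met", -0.30); ld("us-CRP", "met", 0.30)
  ld("Ferritin", "met", 0.20); ld("ALT", "met", 0.20)
  ld("Insulin", "ins", 0.70); ld("HOMA-IR", "ins", 0.70)
  ld("AST", "liv", 0.60); ld("ALT", "liv", 0.60); ld("GGT", "liv", 0.50)
  ld("Alkaline phosphatase", "liv", 0.35)
  ld("Total bilirubin", "liv", 0.20); ld("Direct bilirubin", "liv", 0.20)
  ld("Hemoglobin", "hem", 0.90); ld("Hematocrit", "hem", 0.90)
  ld("Albumin", "hem", 0.20)
  ld("Total cholesterol", "lip", 0.80); ld("LDL-c", "lip", 0.85)
  ld("HDL-c", "lip", 0.35); ld("Triglycerides", "lip", 0.30)
  ld("Total bilirubin", "bil", 0.78); ld("Direct bilirubin", "bil", 0.74)
  ld("fT4", "thy", 0.60); ld("TSH", "thy", -0.50)
  if (group == "case") {
    ld("ALT", "met", 0.35); ld("GGT", "met", 0.30)
    ld("TGF-β", "liv", 0.35); ld("TGF-β", "met", 0.25)
    ld("fT4", "met", -0.45); ld("Vitamin D", "met", -0.25)
    ld("Creatinine", "liv", 0.25)
    ld("Hemoglobin", "liv", 0.25); ld("Hematocrit", "liv", 0.25)
    ld("GGT", "liv", 0.55)
  }
  stopifnot(max(rowSums(B^2)) < 0.99)
  R <- tcrossprod(B)
  diag(R) <- 1
  unname(R)
}

#' Validate a biomarker panel
#'
#' Checks the structural invariants of a panel: required columns present,
#' grade 0 exactly for the no-steatosis group, all non-missing marker
#' concentrations strictly positive. Missing markers are allowed (panels
#' read from disk may carry them); generated panels never do.
#'
#' @param panel a data.frame with the panel schema.
#' @return the panel, invisibly, with class `biomarker_panel`.
#' @export
validate_panel <- function(panel) {
  required <- c("sample_id", "steatosis", "grade")
  miss <- setdiff(required, names(panel))
  if (length(miss))
    stop(sprintf("schema error: missing required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (!all(panel$steatosis %in% c(0L, 1L)))
    stop("validation error: `steatosis` must be coded 0/1", call. = FALSE)
  if (!all(panel$grade %in% c(0L, 1L, 2L)))
    stop("validation error: `grade` must be coded 0/1/2", call. = FALSE)
  bad <- which((panel$grade > 0L) != (panel$steatosis == 1L))
  if (length(bad))
    stop(sprintf(
      "validation error: grade > 0 must hold exactly for steatosis = 1; offending row(s): %s",
      paste(bad, collapse = ", ")), call. = FALSE)
  mm <- marker_matrix(panel)
  if (ncol(mm)) {
    nonpos <- which(!is.na(mm) & mm <= 0, arr.ind = TRUE)
    if (nrow(nonpos))
      stop(sprintf(
        "validation error: non-positive concentration (log10 undefined) at sample %s, marker %s",
        panel$sample_id[nonpos[1, 1]], colnames(mm)[nonpos[1, 2]]),
        call. = FALSE)
  }
  if (!inherits(panel, "biomarker_panel"))
    class(panel) <- c("biomarker_panel", class(panel))
  invisible(panel)
}

#' Marker columns of a panel as a numeric matrix
#'
#' @param panel a biomarker panel.
#' @param include_anthropometrics if `TRUE`, append `bmi_z` and `waist` as
#'   extra columns so they can enter clustering/correlation stages alongside
#'   the markers.
#' @return samples x markers numeric matrix with sample ids as row names.
#' @export
marker_matrix <- function(panel, include_anthropometrics = FALSE) {
  mcols <- setdiff(names(panel), PANEL_RESERVED_COLUMNS)
  m <- as.matrix(as.data.frame(panel, check.names = FALSE)[, mcols, drop = FALSE])
  storage.mode(m) <- "double"
  if (include_anthropometrics)
    m <- cbind(m, bmi_z = panel$bmi_z, waist = panel$waist)
  rownames(m) <- panel$sample_id
  m
}

#' Names of the marker columns of a panel
#' @param panel a biomarker panel.
#' @export
panel_markers <- function(panel) {
  setdiff(names(panel), PANEL_RESERVED_COLUMNS)
}
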