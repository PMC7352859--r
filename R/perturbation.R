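# Degree of Biochemical Perturbation ------------------------------------------
#
# Adaptation of the transcriptomic "molecular degree of perturbation" to a
# biochemical marker panel: each sample's markers are expressed as signed
# deviations from the reference (no steatosis) group's mean in units of the
# reference standard deviation, and a sample's aggregate score is the mean
# absolute deviation across markers. Samples whose score exceeds the
# reference-group mean score by more than two reference-score standard
# deviations are flagged biochemically perturbed.

#' Per-sample and per-marker perturbation scores
#'
#' z[s, m] = (x[s, m] - mean_ref(m)) / sd_ref(m), computed on log10
#' concentrations by default (consistent with every other multivariate
#' stage); the sample score is the mean of |z| over available markers.
#'
#' @param panel a biomarker panel.
#' @param reference which samples form the reference group: "control"
#'   (steatosis == 0, the default) or a logical vector.
#' @param log_scale compute on log10 concentrations (default TRUE).
#' @param aggregate "abs_mean" (default) or "signed_mean".
#' @return object of class `dbp_result`: `z_matrix`, `sample_score`,
#'   `marker_group_score` (per-marker mean |z| per clinical group),
#'   `reference` (logical vector), `excluded_markers`.
#' @export
dbp_scores <- function(panel, reference = "control", log_scale = TRUE,
                       aggregate = c("abs_mean", "signed_mean")) {
  aggregate <- match.arg(aggregate)
  validate_panel(panel)
  ref <- if (identical(reference, "control")) panel$steatosis == 0L
         else as.logical(reference)
  if (sum(ref) < 3L) stop("reference group must have >= 3 samples",
                          call. = FALSE)
  vals <- marker_matrix(panel)
  if (log_scale) vals <- log10(vals)
  mu <- apply(vals[ref, , drop = FALSE], 2, mean, na.rm = TRUE)
  sd_ref <- apply(vals[ref, , drop = FALSE], 2, stats::sd, na.rm = TRUE)
  zero_sd <- !is.na(sd_ref) & sd_ref == 0
  if (all(zero_sd)) stop("reference sd is zero for every marker",
                         call. = FALSE)
  if (any(zero_sd))
    warning(sprintf("excluding marker(s) with zero reference sd: %s",
                    paste(colnames(vals)[zero_sd], collapse = ", ")),
            call. = FALSE)
  keep <- !zero_sd
  z <- sweep(sweep(vals[, keep, drop = FALSE], 2, mu[keep], `-`),
             2, sd_ref[keep], `/`)
  rownames(z) <- panel$sample_id
  score <- if (aggregate == "abs_mean") rowMeans(abs(z), na.rm = TRUE)
           else rowMeans(z, na.rm = TRUE)
  grp <- ifelse(panel$steatosis == 1L, "case", "control")
  mg <- vapply(c("control", "case"), function(g) {
    colMeans(abs(z[grp == g, , drop = FALSE]), na.rm = TRUE)
  }, numeric(ncol(z)))
  structure(list(z_matrix = z,
                 sample_score = stats::setNames(score, panel$sample_id),
                 marker_group_score = mg,
                 reference = ref,
                 group = grp,
                 aggregate = aggregate,
                 excluded_markers = colnames(vals)[zero_sd]),
            class = "dbp_result")
}

#' Flag biochemically perturbed samples
#'
#' Threshold = mean + 2 sd of the reference group's sample scores; samples
#' strictly above it are flagged.
#'
#' @param result a `dbp_result` from [dbp_scores()].
#' @return the result with `threshold` and logical `perturbed` added.
#' @export
classify_perturbed <- function(result) {
  stopifnot(inherits(result, "dbp_result"))
  ref_scores <- result$sample_score[result$reference]
  m <- mean(ref_scores)
  s <- stats::sd(ref_scores)
  if (is.na(s) || s == 0) {
    warning("reference scores are constant; threshold set to their mean",
            call. = FALSE)
    s <- 0
  }
  result$threshold <- m + 2 * s
  result$perturbed <- result$sample_score > result$threshold
  result
}

#' Per-marker fold differences in perturbation between groups
#'
#' Mean |z| per marker in each group, case/control ratio, and
#' Mann-Whitney tests on |z| with Holm adjustment over the marker family.
#'
#' @param result a `dbp_result`.
#' @param alpha familywise level for the significance flag.
#' @return data.frame: marker, mean_abs_z_control, mean_abs_z_case, fold,
#'   p_raw, p_adjusted, significant.
#' @export
dbp_fold_table <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "dbp_result"))
  az <- abs(result$z_matrix)
  is_case <- result$group == "case"
  if (!any(is_case) || !any(!is_case))
    stop("both clinical groups must be present", call. = FALSE)
  p_raw <- vapply(colnames(az), function(m) {
    mann_whitney(az[is_case, m], az[!is_case, m])$p_raw
  }, 1.0)
  out <- data.frame(
    marker = colnames(az),
    mean_abs_z_control = colMeans(az[!is_case, , drop = FALSE], na.rm = TRUE),
    mean_abs_z_case = colMeans(az[is_case, , drop = FALSE], na.rm = TRUE),
    p_raw = unname(p_raw), stringsAsFactors = FALSE)
  out$fold <- out$mean_abs_z_case / out$mean_abs_z_control
  out$p_adjusted <- holm_adjust(out$p_raw)
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  out[, c("marker", "mean_abs_z_control", "mean_abs_z_case", "fold",
          "p_raw", "p_adjusted", "significant")]
}
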