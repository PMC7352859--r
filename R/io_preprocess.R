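# Panel I/O and the log10 + z-score transform ---------------------------------

#' Read a biomarker panel from CSV
#'
#' Expects a UTF-8, comma-separated file with a header. Required columns:
#' `sample_id`, `steatosis`, `grade`. The remaining reserved clinical columns
#' (`sex`, `age`, `bmi_z`, `waist`) are kept as covariates; every other
#' column is a marker. Unparseable marker cells become explicit `NA`s;
#' non-positive concentrations are rejected because every downstream stage
#' works on the log10 scale.
#'
#' @param path CSV file path.
#' @return a validated `biomarker_panel` data.frame, column order preserved.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read panel: '%s'", path),
                               call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  required <- c("sample_id", "steatosis", "grade")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("schema error: missing required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$steatosis <- as.integer(df$steatosis)
  df$grade <- as.integer(df$grade)
  for (col in setdiff(names(df), "sample_id")) {
    if (!is.numeric(df[[col]])) {
      suppressWarnings(df[[col]] <- as.numeric(df[[col]]))
    }
  }
  validate_panel(df)
  class(df) <- c("biomarker_panel", "data.frame")
  df
}

#' Write a biomarker panel to CSV
#'
#' Floats are serialized with 17 significant digits so that a
#' write/read round trip reproduces every value exactly as a double.
#'
#' @param panel a biomarker panel.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  out <- as.data.frame(panel, check.names = FALSE)
  for (col in names(out)) {
    if (is.double(out[[col]]))
      out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Log10-transform and z-score the marker matrix
#'
#' The transform used by every multivariate stage (clustering, networks,
#' perturbation scoring, the sparse canonical discriminant): each marker is
#' log10-transformed and standardized to mean 0, sd 1 (sample sd, n-1)
#' across the retained samples. Constant columns become all zeros with a
#' warning and a recorded sd of 0. The per-marker center and scale are kept
#' so the transform is invertible.
#'
#' @param panel a biomarker panel.
#' @param subset optional logical or integer vector selecting the samples
#'   over which to standardize (e.g. one clinical group).
#' @param include_anthropometrics include `bmi_z` and `waist` as extra
#'   columns (these are z-scored but not log-transformed, as z-scores and
#'   lengths are already interval-scaled).
#' @return an object of class `transformed_panel`: list with `values`
#'   (samples x markers matrix), `center`, `scale` (per-marker log10 mean
#'   and sd), `log_transformed` (per-column flag) and `source` (the panel
#'   rows used).
#' @export
log10_zscore <- function(panel, subset = NULL,
                         include_anthropometrics = FALSE) {
  validate_panel(panel)
  rows <- if (is.null(subset)) seq_len(nrow(panel)) else {
    if (is.logical(subset)) which(subset) else as.integer(subset)
  }
  sub <- panel[rows, , drop = FALSE]
  m <- marker_matrix(sub, include_anthropometrics = FALSE)
  bad <- which(!is.na(m) & m <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-positive value for marker '%s' in sample '%s'",
                 colnames(m)[bad[1, 2]], sub$sample_id[bad[1, 1]]),
         call. = FALSE)
  lm10 <- log10(m)
  logged <- rep(TRUE, ncol(lm10))
  if (include_anthropometrics) {
    lm10 <- cbind(lm10, bmi_z = sub$bmi_z, waist = sub$waist)
    logged <- c(logged, FALSE, FALSE)
  }
  center <- apply(lm10, 2, mean, na.rm = TRUE)
  scale <- apply(lm10, 2, stats::sd, na.rm = TRUE)
  const <- !is.na(scale) & scale == 0
  if (any(const)) {
    warning(sprintf("constant marker column(s) standardized to zero: %s",
                    paste(colnames(lm10)[const], collapse = ", ")),
            call. = FALSE)
  }
  denom <- ifelse(const | is.na(scale), 1, scale)
  values <- sweep(sweep(lm10, 2, center, `-`), 2, denom, `/`)
  values[, const] <- 0
  scale[const] <- 0
  structure(list(values = values, center = center, scale = scale,
                 log_transformed = stats::setNames(logged, colnames(lm10)),
                 source = sub),
            class = "transformed_panel")
}

#' Invert the log10 + z-score transform
#'
#' @param tp a `transformed_panel`.
#' @return matrix of native-unit concentrations (columns that were not
#'   log-transformed are returned on their original scale).
#' @export
inverse_transform <- function(tp) {
  stopifnot(inherits(tp, "transformed_panel"))
  sc <- ifelse(tp$scale == 0, 1, tp$scale)
  raw <- sweep(sweep(tp$values, 2, sc, `*`), 2, tp$center, `+`)
  raw[, tp$log_transformed] <- 10^raw[, tp$log_transformed, drop = FALSE]
  raw
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat(sprintf("<biomarker_panel> %d samples (%d control / %d case), %d markers\n",
              nrow(x), sum(x$steatosis == 0), sum(x$steatosis == 1),
              length(panel_markers(x))))
  NextMethod()
}
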