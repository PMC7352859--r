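# End-to-end analysis pipeline ------------------------------------------------

PIPELINE_STAGES <- c("simulate", "preprocess", "univariate", "clustering",
                     "network", "dbp", "scca", "association")

.stage_deps <- list(
  simulate = character(0),
  preprocess = character(0),
  univariate = "preprocess",
  clustering = "preprocess",
  network = "preprocess",
  dbp = "preprocess",
  scca = "preprocess",
  association = "preprocess"
)

#' Build a pipeline run configuration
#'
#' @param input "simulate" (default) or a path to a panel CSV.
#' @param cohort a [cohort_config()] used when simulating; defaults to
#'   [default_study_config()].
#' @param alpha_network edge inclusion level for correlation networks.
#' @param n_boot bootstrap replicates for clustering and network support.
#' @param scca_penalties length-2 numeric (penalty_u, penalty_v); NULL for
#'   the fit defaults.
#' @param alpha_entry univariate entry threshold for the multivariable
#'   logistic model.
#' @param reference_group reference for the perturbation score ("control").
#' @param roc_marker marker whose single-marker ROC is reported.
#' @param seed single integer governing all randomness in the run.
#' @param output_dir directory for exports.
#' @param stages subset of `PIPELINE_STAGES` to run (dependencies added
#'   automatically; order enforced).
#' @return a `run_config` list.
#' @export
run_config <- function(input = "simulate", cohort = default_study_config(),
                       alpha_network = 0.05, n_boot = 100L,
                       scca_penalties = NULL, alpha_entry = 0.2,
                       reference_group = "control",
                       roc_marker = "TGF-β",
                       seed = 1L, output_dir = tempfile("bioperturb_run_"),
                       stages = PIPELINE_STAGES) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  needed <- unique(unlist(lapply(stages, function(s) c(.stage_deps[[s]], s))))
  if (identical(input, "simulate")) needed <- union("simulate", needed)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% needed]
  structure(list(input = input, cohort = cohort,
                 alpha_network = alpha_network, n_boot = as.integer(n_boot),
                 scca_penalties = scca_penalties,
                 alpha_entry = alpha_entry,
                 reference_group = reference_group,
                 roc_marker = roc_marker,
                 seed = as.integer(seed), output_dir = output_dir,
                 stages = stages),
            class = "run_config")
}

# one deterministic sub-seed per stage, all spawned from the global seed so
# toggling one stage never perturbs another stage's random stream
.stage_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L,
                             length(PIPELINE_STAGES)),
                  PIPELINE_STAGES)
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order on a simulated or
#' loaded panel, writes every stage's outputs under `output_dir`, and
#' returns a machine-readable report. Identical configs produce identical
#' exports.
#'
#' @param config a [run_config()].
#' @return an `analysis_report`: list with `manifest` (stage -> files),
#'   `summary` (headline numbers), `config`, `warnings`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- .stage_seeds(config$seed)
  manifest <- list()
  summary <- list(seed = config$seed)
  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, w)
  out <- function(...) file.path(config$output_dir, sprintf(...))
  emit <- function(stage, path) {
    manifest[[stage]] <<- c(manifest[[stage]], path)
    path
  }
  wcsv <- function(df, path) {
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
    path
  }

  # --- input panel
  if (identical(config$input, "simulate")) {
    panel <- generate_cohort(config$cohort, seed = seeds[["simulate"]])
    if ("simulate" %in% config$stages)
      emit("simulate", write_panel(panel, out("panel.csv")))
  } else {
    panel <- read_panel(config$input)
  }
  run_stage <- function(s) s %in% config$stages

  tp <- NULL
  if (run_stage("preprocess")) {
    tp <- log10_zscore(panel)
    df <- data.frame(sample_id = panel$sample_id, tp$values,
                     check.names = FALSE)
    emit("preprocess", wcsv(df, out("transformed.csv")))
  }

  if (run_stage("univariate")) {
    uni <- univariate_table(panel)
    emit("univariate", wcsv(uni, out("univariate.csv")))
    summary$markers_significant_holm <- uni$marker[uni$significant]
    summary$n_significant_holm <- sum(uni$significant)
  }

  if (run_stage("clustering")) {
    dend <- bootstrap_support(t(tp$values), n_boot = config$n_boot,
                              seed = seeds[["clustering"]])
    emit("clustering",
         write_dendrogram_newick(dend, out("marker_dendrogram.nwk")))
    jsonlite::write_json(
      list(n_boot = dend$n_boot, support = dend$bootstrap_support,
           merge_heights = dend$merge_heights),
      out("marker_dendrogram_support.json"), auto_unbox = TRUE, digits = NA)
    emit("clustering", out("marker_dendrogram_support.json"))
    if (all(c(0L, 1L, 2L) %in% panel$grade)) {
      gp <- grade_profile_matrix(panel)
      emit("clustering", wcsv(data.frame(marker = rownames(gp), gp,
                                         check.names = FALSE),
                              out("grade_profiles.csv")))
      summary$mean_support <- mean(dend$bootstrap_support)
    }
  }

  if (run_stage("network")) {
    nets <- list(
      control = bootstrap_network(panel[panel$steatosis == 0L, ],
                                  group = "control",
                                  alpha = config$alpha_network,
                                  n_boot = config$n_boot,
                                  seed = seeds[["network"]]),
      case = bootstrap_network(panel[panel$steatosis == 1L, ],
                               group = "case",
                               alpha = config$alpha_network,
                               n_boot = config$n_boot,
                               seed = seeds[["network"]] + 1L))
    for (g in names(nets)) {
      emit("network", wcsv(nets[[g]]$edges, out("network_%s_edges.csv", g)))
      emit("network",
           write_network_graphml(nets[[g]], out("network_%s.graphml", g)))
    }
    nd <- node_degree_table(nets)
    emit("network", wcsv(data.frame(marker = rownames(nd$degrees),
                                    nd$degrees, check.names = FALSE),
                         out("node_degrees.csv")))
    emit("network", wcsv(nd$totals, out("network_totals.csv")))
    summary$network_edges <- stats::setNames(nd$totals$n_edges,
                                             nd$totals$group)
    summary$network_negative_edges <- stats::setNames(nd$totals$n_negative,
                                                      nd$totals$group)
  }

  if (run_stage("dbp")) {
    dbp <- withCallingHandlers(
      classify_perturbed(dbp_scores(panel,
                                    reference = config$reference_group)),
      warning = function(w) {
        note(conditionMessage(w)); invokeRestart("muffleWarning")
      })
    emit("dbp", wcsv(data.frame(sample_id = rownames(dbp$z_matrix),
                                dbp$z_matrix, check.names = FALSE),
                     out("dbp_z_matrix.csv")))
    emit("dbp", wcsv(data.frame(sample_id = names(dbp$sample_score),
                                group = dbp$group,
                                score = unname(dbp$sample_score),
                                perturbed = unname(dbp$perturbed)),
                     out("dbp_scores.csv")))
    emit("dbp", wcsv(dbp_fold_table(dbp), out("dbp_fold.csv")))
    mw <- mann_whitney(dbp$sample_score[dbp$group == "case"],
                       dbp$sample_score[dbp$group == "control"])
    summary$dbp_group_p <- mw$p_raw
    summary$dbp_threshold <- dbp$threshold
    summary$dbp_perturbed_fraction <- c(
      control = mean(dbp$perturbed[dbp$group == "control"]),
      case = mean(dbp$perturbed[dbp$group == "case"]))
  }

  if (run_stage("scca")) {
    Y <- group_indicator_matrix(panel$steatosis)
    pu <- config$scca_penalties[1]; pv <- config$scca_penalties[2]
    model <- fit_scca(tp$values, Y, penalty_u = pu, penalty_v = pv)
    cc <- canonical_coefficients(model)
    roc <- scca_discriminant_roc(tp$values, panel$steatosis, model)
    proj <- vector_projection(model, tp$values, Y)
    jsonlite::write_json(
      list(u = as.list(model$u), v = as.list(model$v),
           penalty_u = model$penalty_u, penalty_v = model$penalty_v,
           canonical_correlation = model$canonical_correlation,
           iterations = model$iterations, converged = model$converged),
      out("scca_model.json"), auto_unbox = TRUE, digits = NA)
    emit("scca", out("scca_model.json"))
    emit("scca", wcsv(cc$ranked, out("scca_coefficients.csv")))
    emit("scca", wcsv(data.frame(sample_id = panel$sample_id,
                                 proj$coordinates, check.names = FALSE),
                      out("scca_coordinates.csv")))
    summary$scca_auc <- roc$auc
    summary$scca_auc_ci <- roc$auc_ci
    summary$scca_canonical_correlation <- model$canonical_correlation
    summary$scca_top_markers <- utils::head(cc$ranked$marker, 6)
  }

  if (run_stage("association")) {
    screen <- univariate_screen(panel, alpha_entry = config$alpha_entry)
    emit("association", wcsv(screen, out("univariate_screen.csv")))
    sel_markers <- intersect(screen$variable[screen$selected],
                             panel_markers(panel))
    # forest table: one covariate-adjusted model per screened marker
    # (the reported ORs are "after adjustment for sex, age, BMI z, waist")
    forest <- do.call(rbind, lapply(sel_markers, function(m) {
      fit <- withCallingHandlers(
        fit_logistic(logistic_design(panel, m), panel$steatosis),
        warning = function(w) {
          note(sprintf("%s: %s", m, conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      row <- fit$terms[fit$terms$term == sprintf("log10(%s)", m), ]
      row$marker <- m
      row$separation <- fit$separation
      row
    }))
    emit("association", wcsv(forest, out("forest_table.csv")))
    # the joint multivariable model over all screened markers, with its
    # separation diagnosis, as a secondary export
    model <- withCallingHandlers(
      fit_logistic(logistic_design(panel, sel_markers), panel$steatosis),
      warning = function(w) {
        note(conditionMessage(w)); invokeRestart("muffleWarning")
      })
    emit("association", wcsv(model$terms, out("multivariable_model.csv")))
    roc <- marker_roc(panel, config$roc_marker)
    emit("association",
         wcsv(data.frame(threshold = roc$thresholds,
                         sensitivity = roc$sensitivity,
                         specificity = roc$specificity),
              out("roc_coordinates.csv")))
    jsonlite::write_json(
      list(marker = roc$marker, auc = roc$auc,
           auc_ci = roc$auc_ci, cutoff_native = roc$cutoff_native,
           sensitivity = roc$sens_at_cutoff,
           specificity = roc$spec_at_cutoff),
      out("roc_summary.json"), auto_unbox = TRUE, digits = NA)
    emit("association", out("roc_summary.json"))
    row <- match(config$roc_marker, forest$marker)
    summary$marker_or_per_log10 <- if (is.na(row)) NA_real_
      else forest$odds_ratio[row]
    summary$marker_or_separation <- if (is.na(row)) NA
      else forest$separation[row]
    summary$marker_roc_auc <- roc$auc
    summary$marker_roc_cutoff <- roc$cutoff_native
    summary$logistic_separation <- model$separation
  }

  report <- structure(list(manifest = manifest, summary = summary,
                           config = config, warnings = warnings_log),
                      class = "analysis_report")
  jsonlite::write_json(
    list(stages = names(manifest),
         files = lapply(manifest, function(f) basename(unlist(f))),
         summary = summary, warnings = warnings_log,
         version = as.character(utils::packageVersion("bioperturb"))),
    file.path(config$output_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA)
  for (stage in names(manifest)) {
    for (f in unlist(manifest[[stage]])) {
      if (!file.exists(f) || file.size(f) == 0)
        stop(sprintf("stage '%s' produced a missing or empty output: %s",
                     stage, f), call. = FALSE)
    }
  }
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n")
  cat("  stages run:", paste(names(x$manifest), collapse = ", "), "\n")
  s <- x$summary
  if (!is.null(s$n_significant_holm))
    cat(sprintf("  Holm-significant markers: %d (%s)\n",
                s$n_significant_holm,
                paste(s$markers_significant_holm, collapse = ", ")))
  if (!is.null(s$network_edges))
    cat(sprintf("  network edges: control %d, case %d\n",
                s$network_edges[["control"]], s$network_edges[["case"]]))
  if (!is.null(s$dbp_group_p))
    cat(sprintf("  DBP case vs control Mann-Whitney p: %.3g\n",
                s$dbp_group_p))
  if (!is.null(s$scca_auc))
    cat(sprintf("  sCCA discriminant AUC: %.3f\n", s$scca_auc))
  if (!is.null(s$marker_roc_auc))
    cat(sprintf("  %s ROC AUC: %.3f (cutoff %.1f)\n",
                x$config$roc_marker, s$marker_roc_auc,
                s$marker_roc_cutoff))
  invisible(x)
}
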