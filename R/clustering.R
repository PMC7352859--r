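# Ward hierarchical clustering with bootstrap support -------------------------

#' Ward minimum-variance clustering
#'
#' Agglomerative clustering on Euclidean distances with Ward linkage
#' (`hclust` method `ward.D2`, whose merge heights follow the
#' Lance-Williams recurrence on Euclidean distances so that each merge
#' minimizes the increase in total within-cluster sum of squares).
#' Deterministic given the input row order; equal-height merge candidates
#' are resolved toward the lowest item index.
#'
#' @param mat items x features numeric matrix, no missing values.
#' @return object of class `ward_dendrogram`: the `hclust` fit plus
#'   `leaf_order`, `merge_heights` and the item labels.
#' @export
ward_cluster <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need >= 2 items to cluster", call. = FALSE)
  if (anyNA(mat))
    stop("missing values: apply listwise deletion before clustering",
         call. = FALSE)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("item", seq_len(nrow(mat)))
  hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                      method = "ward.D2")
  structure(list(hclust = hc, leaf_order = hc$order,
                 merge_heights = hc$height, labels = rownames(mat)),
            class = "ward_dendrogram")
}

# all internal-node leaf sets of an hclust, as sorted label vectors
.cluster_leafsets <- function(hc, labels) {
  n <- length(labels)
  sets <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    members <- integer(0)
    stack <- c(hc$merge[k, 1], hc$merge[k, 2])
    while (length(stack)) {
      top <- stack[[1]]; stack <- stack[-1]
      if (top < 0) members <- c(members, -top)
      else stack <- c(stack, hc$merge[top, 1], hc$merge[top, 2])
    }
    sets[[k]] <- sort(labels[members])
  }
  sets
}

#' Bootstrap support for Ward cluster nodes
#'
#' Resamples the feature axis with replacement `n_boot` times (so support
#' for clusters of markers comes from resampling participants), reclusters,
#' and reports for each internal node of the point-estimate tree the
#' proportion of replicate trees containing the identical leaf set.
#'
#' @param mat items x features matrix with >= 3 features.
#' @param n_boot number of bootstrap replicates (default 100).
#' @param seed integer seed for the resampling.
#' @return a `ward_dendrogram` with an extra `bootstrap_support` vector
#'   (one entry per internal node, in merge order).
#' @export
bootstrap_support <- function(mat, n_boot = 100L, seed = NULL) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 3L) stop("need >= 3 features to bootstrap", call. = FALSE)
  if (n_boot < 1L) stop("n_boot must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  dend <- ward_cluster(mat)
  ref_sets <- .cluster_leafsets(dend$hclust, dend$labels)
  keys <- vapply(ref_sets, paste, "", collapse = "\r")
  hits <- stats::setNames(numeric(length(keys)), keys)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    hb <- ward_cluster(mat[, idx, drop = FALSE])
    bk <- unique(vapply(.cluster_leafsets(hb$hclust, hb$labels),
                        paste, "", collapse = "\r"))
    present <- keys %in% bk
    hits[present] <- hits[present] + 1
  }
  dend$bootstrap_support <- unname(hits / n_boot)
  dend$n_boot <- as.integer(n_boot)
  dend
}

#' Grade-profile matrix for severity clustering
#'
#' Per-marker central tendency of log10 concentration within each steatosis
#' grade (0 / 1 / 2), then z-scored across the three group values within
#' each marker row — the matrix clustered to profile how markers track
#' disease severity.
#'
#' @param panel a biomarker panel with all three grade groups non-empty.
#' @param center "median" (default, matching the package's nonparametric
#'   summaries) or "mean".
#' @param include_anthropometrics append `bmi_z` and `waist` rows.
#' @return markers x 3 matrix of row-standardized group profiles.
#' @export
grade_profile_matrix <- function(panel, center = c("median", "mean"),
                                 include_anthropometrics = FALSE) {
  center <- match.arg(center)
  validate_panel(panel)
  grades <- sort(unique(panel$grade))
  if (!all(c(0L, 1L, 2L) %in% panel$grade))
    stop("all three grade groups (0/1/2) must be non-empty", call. = FALSE)
  vals <- log10(marker_matrix(panel))
  if (include_anthropometrics)
    vals <- cbind(vals, bmi_z = panel$bmi_z, waist = panel$waist)
  fun <- if (center == "median") stats::median else mean
  prof <- vapply(c(0L, 1L, 2L), function(g) {
    apply(vals[panel$grade == g, , drop = FALSE], 2, fun, na.rm = TRUE)
  }, numeric(ncol(vals)))
  colnames(prof) <- c("grade0", "grade1", "grade2")
  ctr <- rowMeans(prof)
  sds <- apply(prof, 1, stats::sd)
  z <- (prof - ctr) / ifelse(sds == 0, 1, sds)
  z[sds == 0, ] <- 0
  z
}

#' Export a dendrogram as Newick text
#'
#' @param dend a `ward_dendrogram`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(dend, path) {
  stopifnot(inherits(dend, "ward_dendrogram"))
  phy <- ape::as.phylo(dend$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
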