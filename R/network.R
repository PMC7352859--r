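# Spearman correlation networks per clinical group ----------------------------

#' Pairwise Spearman correlation matrix with p-values
#'
#' Mid-ranks for ties; pairwise-complete observations. P-values come from
#' exact enumeration of rank permutations when a pair has at most
#' `exact_max` tie-free complete observations, and from the t
#' approximation (t = rho * sqrt((n-2)/(1-rho^2)) on n-2 df) otherwise.
#' Pairs with fewer than `min_pairs` complete observations are marked
#' unavailable (NA).
#'
#' @param values samples x markers numeric matrix.
#' @param min_pairs minimum complete pairs for an entry (default 4).
#' @param exact_max maximum n for the exact permutation p (default 7).
#' @return list with matrices `rho`, `p` and `n` (complete pairs).
#' @export
spearman_matrix <- function(values, min_pairs = 4L, exact_max = 7L) {
  values <- as.matrix(values)
  p <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- paste0("m", seq_len(p))
  complete <- !anyNA(values)
  if (complete) {
    n <- nrow(values)
    rmat <- apply(values, 2, rank)
    rho <- stats::cor(rmat)
    pm <- .spearman_p(rho, n, values, exact_max)
    nmat <- matrix(n, p, p)
  } else {
    rho <- matrix(NA_real_, p, p); pm <- matrix(NA_real_, p, p)
    nmat <- matrix(0L, p, p)
    for (i in seq_len(p)) {
      rho[i, i] <- 1; pm[i, i] <- 0
      nmat[i, i] <- sum(!is.na(values[, i]))
      for (j in seq_len(i - 1L)) {
        ok <- !is.na(values[, i]) & !is.na(values[, j])
        nij <- sum(ok)
        nmat[i, j] <- nmat[j, i] <- nij
        if (nij < min_pairs) next
        x <- values[ok, i]; y <- values[ok, j]
        r <- stats::cor(rank(x), rank(y))
        rho[i, j] <- rho[j, i] <- r
        pm[i, j] <- pm[j, i] <- .spearman_p_single(r, x, y, exact_max)
      }
    }
  }
  dimnames(rho) <- dimnames(pm) <- dimnames(nmat) <-
    list(colnames(values), colnames(values))
  diag(pm) <- 0
  list(rho = rho, p = pm, n = nmat)
}

# vectorized t-approximation p over a rho matrix, exact branch per pair
.spearman_p <- function(rho, n, values, exact_max) {
  r <- pmin(pmax(rho, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pm <- 2 * stats::pt(-abs(tstat), df = n - 2)
  pm[abs(r) >= 1] <- 0
  if (n <= exact_max) {
    p <- ncol(values)
    for (i in seq_len(p)) for (j in seq_len(i - 1L)) {
      pm[i, j] <- pm[j, i] <-
        .spearman_p_single(rho[i, j], values[, i], values[, j], exact_max)
    }
  }
  pm
}

.spearman_p_single <- function(r, x, y, exact_max = 7L) {
  n <- length(x)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= exact_max && !ties) {
    rx <- rank(x)
    perms <- .permutations(n)
    ry <- rank(y)
    null_rho <- apply(perms, 1, function(pp) stats::cor(rx, ry[pp]))
    mean(abs(null_rho) >= abs(r) - 1e-12)
  } else {
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(tstat), df = n - 2)
  }
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Build a Spearman correlation network for one clinical group
#'
#' Edges are marker pairs whose Spearman correlation has unadjusted
#' p < `alpha` (the network inclusion rule; multiplicity adjustment can be
#' switched on for users who want familywise control over edges).
#'
#' @param panel_subset a biomarker panel restricted to one clinical group
#'   (>= 5 samples).
#' @param group label stored on the network.
#' @param alpha edge inclusion level (default 0.05).
#' @param include_anthropometrics add `bmi_z` and `waist` as nodes.
#' @param p_adjust "none" (the inclusion rule default), "holm" or "BH".
#' @return object of class `correlation_network`: `group`, `nodes`,
#'   `edges` data.frame (marker_a, marker_b, rho, p_raw, sign), `degrees`,
#'   `n_samples`.
#' @export
build_network <- function(panel_subset, group = "group", alpha = 0.05,
                          include_anthropometrics = FALSE,
                          p_adjust = c("none", "holm", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (nrow(panel_subset) < 5L)
    stop("need >= 5 samples to build a correlation network", call. = FALSE)
  vals <- log10(marker_matrix(panel_subset))
  if (include_anthropometrics)
    vals <- cbind(vals, bmi_z = panel_subset$bmi_z,
                  waist = panel_subset$waist)
  sm <- spearman_matrix(vals)
  nodes <- colnames(sm$rho)
  pr <- ncol(sm$rho)
  ii <- which(upper.tri(sm$rho), arr.ind = TRUE)
  pvals <- sm$p[ii]
  pa <- if (p_adjust == "none") pvals else stats::p.adjust(pvals, p_adjust)
  keep <- !is.na(pa) & pa < alpha
  edges <- data.frame(
    marker_a = nodes[ii[keep, 1]], marker_b = nodes[ii[keep, 2]],
    rho = sm$rho[ii][keep], p_raw = pvals[keep],
    sign = ifelse(sm$rho[ii][keep] >= 0, "+", "-"),
    stringsAsFactors = FALSE)
  deg <- stats::setNames(integer(pr), nodes)
  if (nrow(edges)) {
    tab <- table(factor(c(edges$marker_a, edges$marker_b), levels = nodes))
    deg[] <- as.integer(tab)
  }
  structure(list(group = group, nodes = nodes, edges = edges,
                 degrees = deg, n_samples = nrow(panel_subset),
                 alpha = alpha,
                 n_positive = sum(edges$sign == "+"),
                 n_negative = sum(edges$sign == "-")),
            class = "correlation_network")
}

#' Bootstrap edge support for a correlation network
#'
#' Resamples participants with replacement `n_boot` times; an edge's
#' support is the fraction of replicates in which the pair passes the
#' alpha rule with the same correlation sign. Edges of the point-estimate
#' network are retained regardless of support.
#'
#' @inheritParams build_network
#' @param n_boot replicates (default 100).
#' @param seed integer seed.
#' @return the point-estimate `correlation_network` with a `boot_support`
#'   column on `edges` and `n_boot` recorded.
#' @export
bootstrap_network <- function(panel_subset, group = "group", alpha = 0.05,
                              n_boot = 100L, seed = NULL,
                              include_anthropometrics = FALSE) {
  if (n_boot < 1L) stop("n_boot must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  net <- build_network(panel_subset, group = group, alpha = alpha,
                       include_anthropometrics = include_anthropometrics)
  if (!nrow(net$edges)) {
    net$edges$boot_support <- numeric(0)
    net$n_boot <- as.integer(n_boot)
    return(net)
  }
  key <- paste(net$edges$marker_a, net$edges$marker_b, net$edges$sign)
  hits <- numeric(length(key))
  n <- nrow(panel_subset)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    nb <- build_network(panel_subset[idx, , drop = FALSE], group = group,
                        alpha = alpha,
                        include_anthropometrics = include_anthropometrics)
    if (!nrow(nb$edges)) next
    bk <- paste(nb$edges$marker_a, nb$edges$marker_b, nb$edges$sign)
    hits <- hits + (key %in% bk)
  }
  net$edges$boot_support <- hits / n_boot
  net$n_boot <- as.integer(n_boot)
  net
}

#' Node-degree table across group networks
#'
#' @param networks list of `correlation_network`s over the same node set.
#' @return list with `degrees` (markers x groups matrix) and `totals`
#'   (per-group positive/negative edge counts).
#' @export
node_degree_table <- function(networks) {
  stopifnot(length(networks) >= 1L)
  nodes <- networks[[1]]$nodes
  for (nw in networks) {
    if (!identical(sort(nw$nodes), sort(nodes)))
      stop("networks do not share a common node set", call. = FALSE)
  }
  groups <- vapply(networks, function(nw) nw$group, "")
  deg <- vapply(networks, function(nw) nw$degrees[nodes], numeric(length(nodes)))
  colnames(deg) <- groups
  totals <- data.frame(
    group = groups,
    n_edges = vapply(networks, function(nw) nrow(nw$edges), 1L),
    n_positive = vapply(networks, function(nw) nw$n_positive, 1L),
    n_negative = vapply(networks, function(nw) nw$n_negative, 1L),
    stringsAsFactors = FALSE)
  list(degrees = deg, totals = totals)
}

#' Export a correlation network as GraphML
#'
#' @param network a `correlation_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  stopifnot(inherits(network, "correlation_network"))
  g <- igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = data.frame(name = network$nodes,
                          degree = as.integer(network$degrees),
                          stringsAsFactors = FALSE))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
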