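# Sparse canonical-correlation discriminant -----------------------------------
#
# Rank-1 penalized matrix decomposition of the cross-product M = X'Y:
# maximize u' M v subject to ||u||2 <= 1, ||v||2 <= 1, ||u||1 <= c_u,
# ||v||1 <= c_v, by alternating soft-thresholded updates. With Y a centered
# group-indicator matrix this acts as a discriminant: the canonical score
# X u is the sparse marker combination maximally correlated with group
# membership.

# max_w w'a  s.t. ||w||2 <= 1, ||w||1 <= c: w = S(a, lam)/||S(a, lam)||2
# with lam = 0 if already feasible, else lam found by bisection so the L1
# norm meets c exactly. c must lie in [1, sqrt(length(a))].
.l1_unit_solve <- function(a, c) {
  if (all(a == 0)) return(a)
  soft <- function(lam) sign(a) * pmax(abs(a) - lam, 0)
  unitize <- function(w) w / sqrt(sum(w^2))
  w0 <- unitize(a)
  if (sum(abs(w0)) <= c + 1e-12) return(w0)
  lo <- 0; hi <- max(abs(a))
  for (it in 1:80) {
    lam <- (lo + hi) / 2
    w <- soft(lam)
    if (all(w == 0)) { hi <- lam; next }
    l1 <- sum(abs(unitize(w)))
    if (l1 > c) lo <- lam else hi <- lam
  }
  # take the feasible endpoint and drop numerically-zero coordinates so a
  # budget of exactly 1 yields a true coordinate vector
  w <- soft(hi)
  if (all(w == 0)) w <- soft(lo * (1 - 1e-12))
  w[abs(w) < 1e-11 * max(abs(w))] <- 0
  unitize(w)
}

#' Centered group-indicator matrix for a binary outcome
#'
#' Two columns (one per group), each centered, the Y side of the
#' discriminant canonical correlation.
#'
#' @param labels binary vector (0/1 or two-level factor).
#' @return n x 2 centered indicator matrix.
#' @export
group_indicator_matrix <- function(labels) {
  f <- factor(labels)
  if (nlevels(f) != 2L) stop("labels must have exactly two classes",
                             call. = FALSE)
  Y <- stats::model.matrix(~ f - 1)
  colnames(Y) <- levels(f)
  scale(Y, center = TRUE, scale = FALSE)
}

#' Fit the sparse canonical-correlation discriminant
#'
#' Alternating penalized power iteration on M = X'Y, initialized at the
#' leading singular vectors of M (deterministic). Each update solves the
#' L1/L2-constrained linear subproblem exactly by soft-thresholding with
#' the threshold found by bisection. Feasibility (||u||2 <= 1,
#' ||u||1 <= penalty_u, likewise for v) holds after every iteration, and
#' the objective u' M v is nondecreasing.
#'
#' @param X samples x markers matrix, column-standardized (mean 0, sd 1).
#' @param Y samples x group-indicator matrix (centered columns), e.g. from
#'   [group_indicator_matrix()].
#' @param penalty_u L1 budget for u, in [1, sqrt(ncol(X))]; default
#'   `1 + 0.5 * (sqrt(ncol(X)) - 1)` (moderate sparsity).
#' @param penalty_v L1 budget for v; default sqrt(ncol(Y)) (no sparsity on
#'   the outcome side).
#' @param max_iter,tol iteration cap and convergence tolerance on
#'   max |delta u|.
#' @return object of class `scca_model`: `u`, `v`, `d` (the objective
#'   u'Mv), `canonical_correlation` (Pearson correlation of Xu and Yv),
#'   `scores` (Xu, oriented so the second group scores higher on average),
#'   `penalty_u`, `penalty_v`, `iterations`, `converged`, `objective_path`.
#' @export
fit_scca <- function(X, Y, penalty_u = NULL, penalty_v = NULL,
                     max_iter = 200L, tol = 1e-7) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  p <- ncol(X); q <- ncol(Y)
  cm <- colMeans(X)
  csd <- apply(X, 2, stats::sd)
  if (max(abs(cm)) > 1e-6 ||
      (any(csd > 0) && max(abs(csd[csd > 0] - 1)) > 1e-6))
    stop("X must be column-standardized (mean 0, sd 1); see log10_zscore()",
         call. = FALSE)
  if (is.null(penalty_u)) penalty_u <- 1 + 0.5 * (sqrt(p) - 1)
  if (is.null(penalty_v)) penalty_v <- sqrt(q)
  if (penalty_u < 1 || penalty_v < 1)
    stop("penalties must be >= 1 (the L1 ball must contain an L2-unit vector)",
         call. = FALSE)
  penalty_u <- min(penalty_u, sqrt(p)); penalty_v <- min(penalty_v, sqrt(q))
  M <- crossprod(X, Y)
  if (all(M == 0)) {
    u <- rep(0, p); v <- rep(0, q)
    return(.scca_result(X, Y, u, v, penalty_u, penalty_v, 0L, TRUE,
                        numeric(0), degenerate = TRUE))
  }
  sv <- svd(M, nu = 1, nv = 1)
  u <- .l1_unit_solve(drop(sv$u), penalty_u)
  v <- .l1_unit_solve(drop(sv$v), penalty_v)
  obj <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    u_new <- .l1_unit_solve(drop(M %*% v), penalty_u)
    v_new <- .l1_unit_solve(drop(crossprod(M, u_new)), penalty_v)
    obj <- c(obj, drop(crossprod(u_new, M %*% v_new)))
    if (max(abs(u_new - u)) < tol && max(abs(v_new - v)) < tol) {
      u <- u_new; v <- v_new; converged <- TRUE; break
    }
    u <- u_new; v <- v_new
  }
  .scca_result(X, Y, u, v, penalty_u, penalty_v, iterations, converged, obj)
}

.scca_result <- function(X, Y, u, v, penalty_u, penalty_v, iterations,
                         converged, objective_path, degenerate = FALSE) {
  names(u) <- colnames(X); names(v) <- colnames(Y)
  scores <- drop(X %*% u)
  yscores <- drop(Y %*% v)
  cc <- if (stats::sd(scores) > 0 && stats::sd(yscores) > 0)
    stats::cor(scores, yscores) else NA_real_
  # deterministic orientation: second indicator column loads positively
  flip <- if (length(v) >= 2 && v[2] != 0) sign(v[2]) else
    if (any(u != 0)) sign(u[which.max(abs(u))]) else 1
  if (flip < 0) { u <- -u; v <- -v; scores <- -scores }
  structure(list(u = u, v = v,
                 d = drop(crossprod(u, crossprod(X, Y) %*% v)),
                 canonical_correlation = cc,
                 scores = scores,
                 penalty_u = penalty_u, penalty_v = penalty_v,
                 iterations = iterations, converged = converged,
                 objective_path = objective_path,
                 degenerate = degenerate),
            class = "scca_model")
}

#' Ranked canonical coefficients
#'
#' Markers ranked by the magnitude of their canonical weight; zero-weight
#' markers are listed separately as excluded by the sparsity penalty.
#'
#' @param model an `scca_model`.
#' @return list with `ranked` (data.frame marker, weight, abs_weight) and
#'   `excluded` (character).
#' @export
canonical_coefficients <- function(model) {
  stopifnot(inherits(model, "scca_model"))
  w <- model$u
  nz <- w[w != 0]
  ord <- order(abs(nz), decreasing = TRUE)
  list(ranked = data.frame(marker = names(nz)[ord],
                           weight = unname(nz[ord]),
                           abs_weight = unname(abs(nz[ord])),
                           stringsAsFactors = FALSE),
       excluded = names(w)[w == 0],
       degenerate = isTRUE(model$degenerate) || all(w == 0))
}

#' ROC of the canonical discriminant score
#'
#' Uses the canonical score X u as a classifier score. Resubstitution mode
#' evaluates the training-set scores (optimistic, matching the exploratory
#' use of the model); `loo_cv` refits the model once per left-out sample
#' and scores it out of fit.
#'
#' @param X standardized marker matrix.
#' @param labels binary outcome (1 = case).
#' @param model fitted `scca_model` (required for resubstitution; refit
#'   parameters are taken from it in `loo_cv` mode).
#' @param mode "resubstitution" or "loo_cv".
#' @return an `roc_result` (see [roc_curve()]); in loo mode the scores are
#'   the per-sample out-of-fit canonical scores.
#' @export
scca_discriminant_roc <- function(X, labels, model,
                                  mode = c("resubstitution", "loo_cv")) {
  mode <- match.arg(mode)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("labels must contain both classes", call. = FALSE)
  if (mode == "resubstitution") {
    scores <- model$scores
  } else {
    n <- nrow(X)
    scores <- numeric(n)
    for (i in seq_len(n)) {
      Xi <- scale(X[-i, , drop = FALSE])
      sds <- attr(Xi, "scaled:scale")
      Xi[, sds == 0] <- 0
      Yi <- group_indicator_matrix(labels[-i])
      fit <- fit_scca(Xi, Yi, penalty_u = model$penalty_u,
                      penalty_v = model$penalty_v)
      ctr <- attr(Xi, "scaled:center")
      xi <- (X[i, ] - ctr) / ifelse(sds == 0, 1, sds)
      scores[i] <- sum(xi * fit$u)
    }
  }
  roc_curve(scores, labels)
}

#' Two-dimensional canonical projection with marker direction vectors
#'
#' The second canonical pair comes from the rank-1-deflated cross-product
#' M - d u v'. Sample coordinates are the scores on the two canonical
#' variates; each marker's direction vector is its correlation with the
#' two variates.
#'
#' @param model fitted first-pair `scca_model`.
#' @param X standardized marker matrix the model was fitted on.
#' @param Y the centered indicator matrix used in the fit.
#' @return list with `coordinates` (n x 2), `marker_vectors` (p x 2
#'   correlations), `second_pair` (`scca_model` or NULL when the deflated
#'   matrix is numerically rank-0, flagged `degenerate`).
#' @export
vector_projection <- function(model, X, Y) {
  stopifnot(inherits(model, "scca_model"))
  X <- as.matrix(X); Y <- as.matrix(Y)
  M <- crossprod(X, Y)
  M2 <- M - model$d * tcrossprod(model$u, model$v)
  degenerate <- sqrt(sum(M2^2)) < 1e-8 * max(1, sqrt(sum(M^2)))
  second <- NULL
  s2 <- rep(0, nrow(X))
  if (!degenerate) {
    sv <- svd(M2, nu = 1, nv = 1)
    u2 <- .l1_unit_solve(drop(sv$u), model$penalty_u)
    v2 <- .l1_unit_solve(drop(sv$v), model$penalty_v)
    for (it in 1:200) {
      u_new <- .l1_unit_solve(drop(M2 %*% v2), model$penalty_u)
      v_new <- .l1_unit_solve(drop(crossprod(M2, u_new)), model$penalty_v)
      if (max(abs(u_new - u2)) < 1e-7 && max(abs(v_new - v2)) < 1e-7) {
        u2 <- u_new; v2 <- v_new; break
      }
      u2 <- u_new; v2 <- v_new
    }
    second <- .scca_result(X, Y, u2, v2, model$penalty_u, model$penalty_v,
                           it, TRUE, numeric(0))
    s2 <- second$scores
  }
  coords <- cbind(cv1 = model$scores, cv2 = s2)
  mv <- t(apply(X, 2, function(col) {
    c(cv1 = if (stats::sd(col) > 0 && stats::sd(coords[, 1]) > 0)
        stats::cor(col, coords[, 1]) else 0,
      cv2 = if (stats::sd(col) > 0 && stats::sd(coords[, 2]) > 0)
        stats::cor(col, coords[, 2]) else 0)
  }))
  list(coordinates = coords, marker_vectors = mv,
       second_pair = second, degenerate = degenerate)
}
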