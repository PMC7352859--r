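# Shared fixtures: small configurable cohorts built in code.

# p independent markers, no group effect: the null configuration
null_config <- function(p = 25L, n_control = 36L, n_case = 36L,
                        sd = 0.2) {
  cp <- default_covariate_params()
  cp$coupling$coef <- 0
  cohort_config(
    n_control = n_control, n_case = n_case,
    grade_split = c(ceiling(n_case / 2), floor(n_case / 2)),
    marker_names = paste0("M", seq_len(p)),
    log10_means_control = rep(1, p), log10_sds = rep(sd, p),
    covariate_params = cp)
}

# one shifted marker among independent nulls
shift_config <- function(shift = 1.0, sd = 0.5, p = 5L,
                         n_control = 36L, n_case = 36L) {
  cfg <- null_config(p = p, n_control = n_control, n_case = n_case, sd = sd)
  cfg$effect_log10[1] <- shift
  cfg
}

# tiny panel from an explicit marker matrix (rows = samples)
panel_from_matrix <- function(m, steatosis, grade = NULL) {
  n <- nrow(m)
  if (is.null(grade)) grade <- ifelse(steatosis == 1L, 1L, 0L)
  df <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                   steatosis = as.integer(steatosis),
                   grade = as.integer(grade),
                   sex = rep_len(c(0L, 1L), n),
                   age = seq(10, 16, length.out = n),
                   bmi_z = seq(1.5, 3, length.out = n),
                   waist = seq(75, 95, length.out = n),
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("M", seq_len(ncol(m)))
  cbind(df, as.data.frame(m))
}

# brute-force Holm step-down, written independently of p.adjust
holm_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    val <- (m - i + 1) * p[ord[i]]
    running <- max(running, val)
    adj[ord[i]] <- min(1, running)
  }
  adj
}

# naive Lance-Williams Ward recurrence on Euclidean distances
ward_heights_oracle <- function(mat) {
  d <- as.matrix(dist(mat))
  n <- nrow(d)
  size <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(active)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (d[active[i], active[j]] < best[1] - 1e-12) {
        best <- c(d[active[i], active[j]], i, j)
      }
    }
    i <- best[2]; j <- best[3]
    a <- active[i]; b <- active[j]
    heights[step] <- d[a, b]
    ni <- size[a]; nj <- size[b]
    for (t in active[-c(i, j)]) {
      nk <- size[t]
      d_new <- sqrt(((ni + nk) * d[a, t]^2 + (nj + nk) * d[b, t]^2 -
                       nk * d[a, b]^2) / (ni + nj + nk))
      d[a, t] <- d[t, a] <- d_new
    }
    size[a] <- ni + nj
    active <- active[-j]
  }
  heights
}

# exact two-sided Mann-Whitney p by enumerating group assignments
mw_exact_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_of <- function(ix) {
    xx <- pooled[ix]; yy <- pooled[-ix]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_of(seq_len(nx))
  n <- nx + ny
  combs <- combn(n, nx)
  us <- apply(combs, 2, u_of)
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# brute-force grid oracle for max u' M v over the L2/L1 feasible sets,
# multi-started over a dense spherical grid (3-dim u, 2-dim v)
scca_objective_oracle <- function(M, cu, cv, n_theta = 360L) {
  stopifnot(nrow(M) == 3, ncol(M) == 2)
  th <- seq(0, 2 * pi, length.out = 4L * n_theta)
  V <- cbind(cos(th), sin(th))
  V <- V[rowSums(abs(V)) <= cv + 1e-9, , drop = FALSE]
  a1 <- seq(0, pi, length.out = n_theta)
  a2 <- seq(0, 2 * pi, length.out = 2L * n_theta)
  U <- cbind(sin(rep(a1, each = length(a2))) * cos(rep(a2, length(a1))),
             sin(rep(a1, each = length(a2))) * sin(rep(a2, length(a1))),
             cos(rep(a1, each = length(a2))))
  U <- U[rowSums(abs(U)) <= cu + 1e-9, , drop = FALSE]
  best <- -Inf
  block <- 10L
  for (start in seq(1, nrow(V), by = block)) {
    vb <- V[start:min(start + block - 1L, nrow(V)), , drop = FALSE]
    W <- M %*% t(vb)                     # 3 x b
    best <- max(best, max(U %*% W))
  }
  best
}
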