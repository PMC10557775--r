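# Independent brute-force oracles used to validate the estimation and
# testing paths. These deliberately avoid the package's QR/closed-form
# machinery: plain SSE evaluation, naive ECDFs, explicit enumeration.

# 3-parameter grid search for the single cosinor: pure SSE evaluation over
# (M, A, peak), refined around the incumbent until the grid is finer than
# `final_step`.
grid_cosinor_oracle <- function(times, values, period = 24,
                                final_step = 1e-5) {
  w <- 2 * pi / period
  sse <- function(M, A, phi) {
    sum((values - (M + A * cos(w * (times - phi))))^2)
  }
  m_rng <- c(0, 4); a_rng <- c(0, 2); p_rng <- c(0, period)
  step_m <- 0.05; step_p <- 0.25
  repeat {
    ms <- seq(m_rng[1], m_rng[2], by = step_m)
    as <- seq(a_rng[1], a_rng[2], by = step_m)
    ps <- seq(p_rng[1], p_rng[2], by = step_p)
    vals <- expand.grid(M = ms, A = as, phi = ps)
    ss <- mapply(sse, vals$M, vals$A, vals$phi)
    best <- unlist(vals[which.min(ss), ])
    if (step_m <= final_step && step_p <= final_step) break
    step_m <- max(step_m / 10, final_step)
    step_p <- max(step_p / 10, final_step)
    m_rng <- best[["M"]] + c(-12, 12) * step_m
    a_rng <- pmax(0, best[["A"]] + c(-12, 12) * step_m)
    p_rng <- best[["phi"]] + c(-12, 12) * step_p
  }
  best
}

# Profiled grid search for one group of the joint model: for each candidate
# peak hour solve the 2-parameter (M, A) least squares by explicit normal
# equations, then refine the phase grid.
grid_joint_group_oracle <- function(times, values, period = 24,
                                    coarse = 0.01, fine = 5e-4) {
  w <- 2 * pi / period
  solve_at <- function(phi) {
    x <- cos(w * (times - phi))
    n <- length(values)
    sx <- sum(x); sxx <- sum(x^2); sy <- sum(values); sxy <- sum(x * values)
    det <- n * sxx - sx^2
    M <- (sxx * sy - sx * sxy) / det
    A <- (n * sxy - sx * sy) / det
    c(M = M, A = A, sse = sum((values - M - A * x)^2))
  }
  search <- function(phis) {
    res <- vapply(phis, solve_at, numeric(3))
    i <- which.min(res["sse", ])
    c(phi = phis[i], res[c("M", "A"), i])
  }
  b1 <- search(seq(0, period - coarse, by = coarse))
  b2 <- search(seq(b1[["phi"]] - 2 * coarse, b1[["phi"]] + 2 * coarse,
                   by = fine))
  out <- c(M = b2[["M"]], A = b2[["A"]], phi = b2[["phi"]] %% period)
  if (out[["A"]] < 0) {
    out[["A"]] <- -out[["A"]]
    out[["phi"]] <- (out[["phi"]] + period / 2) %% period
  }
  out
}

# Normal-equations least squares (no QR): BIC for a design matrix.
bic_normal_eq_oracle <- function(X, y, n_par) {
  co <- solve(t(X) %*% X, t(X) %*% y)
  sse <- sum((y - X %*% co)^2)
  n <- length(y)
  n * log(sse / n) + n_par * log(n)
}

# Direct Benjamini-Hochberg: q_(i) = min_{j >= i} m p_(j) / j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Exact two-sided rank-sum p by full enumeration of all C(n+m, n) rank
# assignments (no ties assumed).
ranksum_enum_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  all_u <- apply(utils::combn(n + m, n), 2,
                 function(ix) sum(ix) - n * (n + 1) / 2)
  p_lo <- mean(all_u <= u_obs)
  p_hi <- mean(all_u >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Naive Kuiper statistic: evaluate both ECDFs at every pooled point.
kuiper_stat_oracle <- function(x, y, period = 24) {
  x <- x %% period; y <- y %% period
  pts <- sort(unique(c(x, y)))
  Fn <- vapply(pts, function(t) mean(x <= t), 0)
  Gm <- vapply(pts, function(t) mean(y <= t), 0)
  max(c(Fn - Gm, 0)) + max(c(Gm - Fn, 0))
}

# Exact Kuiper relabeling p by enumeration of all C(n+m, n) relabelings.
kuiper_enum_oracle <- function(x, y, period = 24) {
  z <- c(x, y) %% period
  n <- length(x); m <- length(y)
  v_obs <- kuiper_stat_oracle(x, y, period)
  vs <- apply(utils::combn(n + m, n), 2, function(ix) {
    kuiper_stat_oracle(z[ix], z[-ix], period)
  })
  mean(vs >= v_obs - 1e-12)
}

# Small fully-annotated two-group dataset built from the cosinor model
# (no noise unless asked): returns list(expr, samples) for `n_genes` genes
# with per-gene parameter tables.
make_two_group_matrix <- function(params_young, params_old,
                                  timepoints = seq(32, 58, 2),
                                  subjects = 2, period = 24, noise_sd = 0,
                                  seed = NULL) {
  build <- function() {
    samples <- tidyr::expand_grid(
      group = c("young", "old"), subject = LETTERS[seq_len(subjects)],
      time_h = timepoints
    ) |>
      dplyr::mutate(sample_id = paste0(group, "_", subject, "_t", time_h),
                    .before = 1)
    w <- 2 * pi / period
    G <- nrow(params_young)
    mat <- matrix(0, G, nrow(samples))
    for (j in seq_len(nrow(samples))) {
      p <- if (samples$group[j] == "young") params_young else params_old
      mat[, j] <- p$mesor + p$amp * cos(w * (samples$time_h[j] - p$peak))
    }
    if (noise_sd > 0) mat <- mat + rnorm(length(mat), 0, noise_sd)
    dimnames(mat) <- list(sprintf("g%03d", seq_len(G)), samples$sample_id)
    expr <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(mat)),
                             tibble::as_tibble(mat))
    list(expr = expr, samples = samples)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}
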