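# --- four-model BIC machinery --------------------------------------------

# The four candidate models all carry group-specific intercepts; they differ
# only in which groups receive rhythm (cos/sin) terms:
#   both       : muY, muO, betaY, gammaY, betaO, gammaO   (6 mean params)
#   young_only : muY, muO, betaY, gammaY                  (4)
#   old_only   : muY, muO, betaO, gammaO                  (4)
#   neither    : muY, muO                                 (2)
# BIC = n log(SSE/n) + p log(n), with p = mean parameters + 1 (variance).
.MODEL_NAMES <- c("both", "neither", "young_only", "old_only")

.model_designs <- function(time, old, period) {
  X <- .joint_design(time, old, period)
  list(
    both = X,
    neither = X[, 1:2, drop = FALSE],
    young_only = X[, c("muY", "muO", "betaY", "gammaY"), drop = FALSE],
    old_only = X[, c("muY", "muO", "betaO", "gammaO"), drop = FALSE]
  )
}

# SSE of OLS for each gene (columns of Yt) under design X
.sse_ols <- function(X, Yt) {
  C <- qr.coef(qr(X), Yt)
  colSums((Yt - X %*% C)^2)
}

# Schwarz weights from a genes x 4 BIC matrix. SSE = 0 gives BIC = -Inf;
# among -Inf models the most parsimonious wins (the penalty dominates in
# the limit of vanishing residual variance).
.bic_weights <- function(bic, n_par) {
  t(apply(bic, 1, function(b) {
    if (any(is.infinite(b) & b < 0)) {
      w <- rep(0, length(b))
      inf <- which(is.infinite(b) & b < 0)
      w[inf[which.min(n_par[inf])]] <- 1
      return(w)
    }
    d <- b - min(b)
    e <- exp(-d / 2)
    e / sum(e)
  }))
}

#' Four-model rhythmicity classification for one series
#'
#' Fits four nested cosinor models — rhythmic in both groups, in young only,
#' in old only, or in neither — all with group-specific intercepts, and
#' converts their BIC values into normalized Schwarz weights
#' `w_m = exp(-(BIC_m - BIC_min)/2) / sum_j exp(-(BIC_j - BIC_min)/2)`,
#' interpretable as model plausibilities on \[0, 1\]. The series is assigned
#' the class of the best model when its weight exceeds `threshold`,
#' otherwise `unclassified`.
#'
#' @inheritParams fit_joint_cosinor
#' @param threshold Weight required to assign a class (default 0.75).
#' @return One-row tibble: four `bic_*` columns, four `w_*` columns,
#'   `class`, `threshold`.
#' @export
fit_four_models <- function(times, values, group, period = 24,
                            threshold = 0.75) {
  stopifnot(length(times) == length(values), length(group) == length(values))
  Y <- matrix(values, nrow = 1, dimnames = list("series", NULL))
  .four_model_engine(Y, times, as.character(group), period, threshold)
}

.four_model_engine <- function(Y, time, group, period = 24, threshold = 0.75) {
  old <- group == "old"
  if (!any(old) || all(old)) abort("Both groups must be present.")
  n <- ncol(Y)
  if (n < 8) abort("At least 8 observations are required.")
  designs <- .model_designs(time, old, period)
  n_par <- c(both = 7, neither = 3, young_only = 5, old_only = 5)
  Yt <- t(Y)
  colnames(Yt) <- NULL
  eps <- 1e-12 * n

  bic <- vapply(.MODEL_NAMES, function(m) {
    sse <- .sse_ols(designs[[m]], Yt)
    ifelse(sse <= eps, -Inf, n * log(sse / n) + n_par[[m]] * log(n))
  }, numeric(nrow(Y)))
  if (is.null(dim(bic))) bic <- matrix(bic, nrow = 1,
                                       dimnames = list(NULL, .MODEL_NAMES))

  # zero-variance genes carry no rhythm information: neither, weight 1
  zero_var <- unname(apply(Y, 1, function(v) var(v) == 0))
  w <- .bic_weights(bic, n_par[.MODEL_NAMES])
  colnames(w) <- .MODEL_NAMES
  if (any(zero_var)) {
    w[zero_var, ] <- 0
    w[zero_var, "neither"] <- 1
  }

  best <- .MODEL_NAMES[max.col(w, ties.method = "first")]
  wmax <- w[cbind(seq_len(nrow(w)), max.col(w, ties.method = "first"))]
  cls <- ifelse(wmax > threshold, best, "unclassified")

  col <- function(mat, nm) unname(mat[, nm])
  tibble::tibble(
    gene_id = rownames(Y) %||% sprintf("gene_%05d", seq_len(nrow(Y))),
    bic_both = col(bic, "both"), bic_neither = col(bic, "neither"),
    bic_young_only = col(bic, "young_only"),
    bic_old_only = col(bic, "old_only"),
    w_both = col(w, "both"), w_neither = col(w, "neither"),
    w_young_only = col(w, "young_only"), w_old_only = col(w, "old_only"),
    class = unname(cls), threshold = threshold
  )
}

#' Classify every gene of an expression matrix by BIC weight
#'
#' Runs the four-model comparison of [fit_four_models()] on every gene of an
#' annotated expression matrix. Genes whose best model reaches a Schwarz
#' weight above `threshold` are called `both`, `young_only` (loss of
#' rhythmicity with age), `old_only` (gain) or `neither`; the rest are
#' `unclassified`. Zero-variance genes are called `neither` with weight 1.
#'
#' @inheritParams diff_rhythm_table
#' @param threshold Weight required to assign a class (default 0.75).
#' @return Tibble, one row per gene, with the four BICs, the four weights,
#'   `class` and `threshold`.
#' @export
classify_matrix <- function(expr, samples, threshold = 0.75, period = 24) {
  mat <- .align_samples(.as_expr_matrix(expr), samples)
  .four_model_engine(mat, samples$time_h, samples$group, period, threshold)
}
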