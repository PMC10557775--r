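#' Tidy a cosinor fit
#'
#' @param x A `cosinor_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per rhythm parameter (`mesor`, `amplitude`,
#'   `peak_hour`) and columns `term`, `estimate`, `std.error`.
#' @export
tidy.cosinor_fit <- function(x, ...) {
  tibble::tibble(
    term = c("mesor", "amplitude", "peak_hour"),
    estimate = c(x$mesor, x$amplitude, x$peak_hour),
    std.error = unname(x$se[c("mesor", "amplitude", "peak_hour")])
  )
}

#' Summarize a cosinor fit in one row
#'
#' @param x A `cosinor_fit` object.
#' @param ... Unused.
#' @return One-row tibble: `p_rhythm`, `residual_sd`, `n_obs`, `period`.
#' @export
glance.cosinor_fit <- function(x, ...) {
  tibble::tibble(p_rhythm = x$p_rhythm, residual_sd = x$residual_sd,
                 n_obs = x$n_obs, period = x$period)
}

#' Tidy a joint two-group cosinor fit
#'
#' @param x A `joint_cosinor` object.
#' @param ... Unused.
#' @return Tibble with one row per parameter: the young-group estimates and
#'   the old-minus-young differences with standard errors and p-values.
#' @export
tidy.joint_cosinor <- function(x, ...) {
  r <- x$result
  tibble::tibble(
    term = c("mesor_diff", "amp_diff", "phase_diff"),
    young = c(r$mesor_young, r$amp_young, r$peak_young),
    old = c(r$mesor_old, r$amp_old, r$peak_old),
    estimate = c(r$mesor_diff, r$amp_diff, r$phase_diff),
    std.error = c(r$se_mesor_diff, r$se_amp_diff, r$se_phase_diff),
    p.value = c(r$p_mesor_diff, r$p_amp_diff, r$p_phase_diff)
  )
}

#' Summarize a joint cosinor fit in one row
#'
#' @param x A `joint_cosinor` object.
#' @param ... Unused.
#' @return One-row tibble: per-group rhythmicity p-values, `n_obs`,
#'   `converged`.
#' @export
glance.joint_cosinor <- function(x, ...) {
  r <- x$result
  tibble::tibble(p_rhythm_young = r$p_rhythm_young,
                 p_rhythm_old = r$p_rhythm_old,
                 n_obs = r$n_obs, converged = r$converged)
}
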