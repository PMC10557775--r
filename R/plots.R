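#' Plot a cosinor fit
#'
#' Shows the observations against time (folded on the period) with the
#' fitted cosine curve overlaid.
#'
#' @param object A `cosinor_fit` object.
#' @param fold Fold times onto one period (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cosinor_fit <- function(object, fold = TRUE, ...) {
  d <- object$data
  tau <- object$period
  if (fold) d$time <- d$time %% tau
  grid <- tibble::tibble(time = seq(0, tau, length.out = 200))
  w <- .omega(tau)
  grid$value <- object$mesor +
    object$amplitude * cos(w * (grid$time - object$peak_hour))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "#2166ac", linewidth = 0.8) +
    ggplot2::labs(x = sprintf("time (h mod %g)", tau), y = "value",
                  title = sprintf("MESOR %.3g, amplitude %.3g, peak %.3g h",
                                  object$mesor, object$amplitude,
                                  object$peak_hour)) +
    ggplot2::theme_minimal()
}

#' Plot a joint two-group cosinor fit
#'
#' @param object A `joint_cosinor` object.
#' @param ... Unused.
#' @return A ggplot object with one fitted curve per group.
#' @export
autoplot.joint_cosinor <- function(object, ...) {
  r <- object$result
  tau <- object$period
  w <- .omega(tau)
  d <- object$data
  d$time <- d$time %% tau
  grid <- tidyr::expand_grid(group = c("young", "old"),
                             time = seq(0, tau, length.out = 200)) |>
    dplyr::mutate(value = ifelse(
      .data$group == "young",
      r$mesor_young + r$amp_young * cos(w * (.data$time - r$peak_young)),
      r$mesor_old + r$amp_old * cos(w * (.data$time - r$peak_old))
    ))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value,
                                  colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, linewidth = 0.8) +
    ggplot2::scale_colour_manual(values = c(young = "#2166ac",
                                            old = "#b2182b")) +
    ggplot2::labs(x = sprintf("time (h mod %g)", tau), y = "value") +
    ggplot2::theme_minimal()
}

#' Bar chart of rhythm-class counts
#'
#' @param weights Output of [classify_matrix()].
#' @return A ggplot object.
#' @export
plot_class_counts <- function(weights) {
  counts <- weights |> dplyr::count(.data$class)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$class, y = .data$n)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "rhythm class (BIC weight)", y = "genes") +
    ggplot2::theme_minimal()
}

#' Fold-change scatter of parameter differences
#'
#' Plots the log2 fold change of the MESOR or the amplitude against the
#' -log10 difference q-value for genes rhythmic in both groups, with the
#' direction-of-change calls coloured.
#'
#' @param records Output of [categorize_genes()].
#' @param parameter `"mesor"` or `"amplitude"`.
#' @return A ggplot object.
#' @export
plot_fold_changes <- function(records, parameter = c("mesor", "amplitude")) {
  parameter <- match.arg(parameter)
  d <- records |> dplyr::filter(.data$rhythm_class == "both")
  if (parameter == "mesor") {
    d <- d |> dplyr::mutate(fc = .data$mesor_log2fc,
                            q = .data$q_mesor_diff,
                            change = .data$mesor_change)
  } else {
    d <- d |> dplyr::mutate(fc = .data$amp_log2fc,
                            q = .data$q_amp_diff,
                            change = .data$amp_change)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fc, y = -log10(.data$q),
                                  colour = .data$change)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(up = "#b2182b", down = "#2166ac",
                                            none = "grey60")) +
    ggplot2::labs(x = sprintf("%s log2 fold change (old / young)", parameter),
                  y = "-log10 q") +
    ggplot2::theme_minimal()
}
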