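#' Categorize genes by rhythm class and parameter changes
#'
#' Combines the differential-cosinor table and the BIC-weight classification
#' into per-gene category records. Direction-of-change calls (MESOR up/down,
#' amplitude up/down, phase advance/delay) are made only for genes whose BIC
#' class is `both` and whose corresponding difference q-value falls below
#' `q_cut`; all other genes carry `none`. Fold changes are expressed in log2
#' units: the MESOR difference (log10 scale) is converted by `log2(10)`, the
#' amplitude change as `log2(amp_old / amp_young)`.
#'
#' @param diff Output of [diff_rhythm_table()].
#' @param weights Output of [classify_matrix()] on the same genes.
#' @param q_cut BH q-value cutoff for difference calls (default 0.05).
#' @param mesor_fc_cut Absolute log2 fold-change filter for MESOR changes
#'   (default 0.25).
#' @param amp_fc_cut Absolute log2 fold-change filter for amplitude changes
#'   (default 0.1).
#' @return Tibble, one row per gene: `gene_id`, `rhythm_class`,
#'   `mesor_change`, `amp_change`, `phase_change`, `mesor_log2fc`,
#'   `amp_log2fc`, `passes_mesor_fc_filter`, `passes_amp_fc_filter`, plus
#'   the underlying differences and q-values.
#' @export
categorize_genes <- function(diff, weights, q_cut = 0.05,
                             mesor_fc_cut = 0.25, amp_fc_cut = 0.1) {
  if (!setequal(diff$gene_id, weights$gene_id)) {
    abort("`diff` and `weights` must cover the same set of genes.")
  }
  dplyr::inner_join(
    diff |>
      dplyr::select("gene_id", "mesor_diff", "amp_young", "amp_old",
                    "amp_diff", "phase_diff",
                    "q_mesor_diff", "q_amp_diff", "q_phase_diff"),
    weights |> dplyr::select("gene_id", rhythm_class = "class"),
    by = "gene_id"
  ) |>
    dplyr::mutate(
      is_both = .data$rhythm_class == "both",
      mesor_change = dplyr::case_when(
        .data$is_both & .data$q_mesor_diff < q_cut & .data$mesor_diff > 0 ~ "up",
        .data$is_both & .data$q_mesor_diff < q_cut & .data$mesor_diff < 0 ~ "down",
        TRUE ~ "none"
      ),
      amp_change = dplyr::case_when(
        .data$is_both & .data$q_amp_diff < q_cut & .data$amp_diff > 0 ~ "up",
        .data$is_both & .data$q_amp_diff < q_cut & .data$amp_diff < 0 ~ "down",
        TRUE ~ "none"
      ),
      phase_change = dplyr::case_when(
        .data$is_both & .data$q_phase_diff < q_cut & .data$phase_diff < 0 ~ "advance",
        .data$is_both & .data$q_phase_diff < q_cut & .data$phase_diff > 0 ~ "delay",
        TRUE ~ "none"
      ),
      mesor_log2fc = .data$mesor_diff * log2(10),
      amp_log2fc = dplyr::if_else(
        .data$is_both & .data$amp_young > 0,
        log2(.data$amp_old / .data$amp_young), NA_real_
      ),
      amp_fc_flagged = .data$is_both & .data$amp_young <= 0,
      passes_mesor_fc_filter = .data$mesor_change != "none" &
        abs(.data$mesor_log2fc) > mesor_fc_cut,
      passes_amp_fc_filter = .data$amp_change != "none" &
        !is.na(.data$amp_log2fc) & abs(.data$amp_log2fc) > amp_fc_cut,
      is_both = NULL
    )
}

#' Three-round heatmap normalization
#'
#' Normalizes an expression matrix for heatmap display, per gene:
#' (1) divide each value by its mean within each (group, serum subject)
#' block, to absorb baseline differences between sera; (2) collapse the
#' replicate sera at each (group, timepoint) by their mean; (3) z-score
#' across timepoints within each group. Used for visualization only, not
#' for inference.
#'
#' @param expr Wide expression tibble (`gene_id` + sample columns).
#' @param samples Sample sheet with `sample_id`, `group`, `subject`,
#'   `time_h`.
#' @return Long tibble: `gene_id`, `group`, `time_h`, `value` (z-score) and
#'   `flagged` (TRUE where a zero block mean in round 1 or a zero SD in
#'   round 3 forced the values to 0).
#' @export
heatmap_normalize <- function(expr, samples) {
  if (!"subject" %in% names(samples)) {
    abort("`samples` must contain a `subject` column for the per-serum blocks.")
  }
  mat <- .align_samples(.as_expr_matrix(expr), samples)

  long <- tibble::as_tibble(mat, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id") |>
    dplyr::left_join(samples, by = "sample_id")

  long |>
    # round 1: mean-normalize within (gene, group, subject)
    dplyr::mutate(
      block_mean = mean(.data$value),
      flag1 = .data$block_mean == 0,
      value = dplyr::if_else(.data$flag1, 0, .data$value / .data$block_mean),
      .by = c("gene_id", "group", "subject")
    ) |>
    # round 2: collapse replicate sera per (group, timepoint)
    dplyr::summarise(
      value = mean(.data$value),
      flag1 = any(.data$flag1),
      .by = c("gene_id", "group", "time_h")
    ) |>
    # round 3: z-score across timepoints within each group
    dplyr::mutate(
      sd_ = sd(.data$value),
      flagged = .data$flag1 | .data$sd_ == 0,
      value = dplyr::if_else(.data$sd_ == 0, 0,
                             (.data$value - mean(.data$value)) / .data$sd_),
      .by = c("gene_id", "group")
    ) |>
    dplyr::select("gene_id", "group", "time_h", "value", "flagged") |>
    dplyr::arrange(.data$gene_id, .data$group, .data$time_h)
}

# subset definitions shared by export_subsets() and the category summary
.subset_filters <- function(records) {
  list(
    rhythmic_both = records$rhythm_class == "both",
    loss_of_rhythmicity = records$rhythm_class == "young_only",
    gain_of_rhythmicity = records$rhythm_class == "old_only",
    mesor_decrease = records$mesor_change == "down",
    mesor_increase = records$mesor_change == "up",
    phase_advance = records$phase_change == "advance",
    phase_delay = records$phase_change == "delay"
  )
}

#' Export gene-list subsets for enrichment tools
#'
#' Writes seven plain-text gene lists (one gene ID per line) from a category
#' table: genes rhythmic in both groups, loss of rhythmicity (rhythmic in
#' young only), gain of rhythmicity (old only), decreased MESOR, increased
#' MESOR, phase advance, and phase delay. These are the inputs downstream
#' enrichment tools (STRING, IPA, LISA and the like) consume.
#'
#' @param records Output of [categorize_genes()].
#' @param dir Output directory (created if missing).
#' @return Tibble with `category`, `n_genes` and `path`, invisibly.
#' @export
export_subsets <- function(records, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  filters <- .subset_filters(records)
  res <- purrr::imap_dfr(filters, function(keep, name) {
    ids <- unique(records$gene_id[keep])
    path <- file.path(dir, paste0(name, ".txt"))
    writeLines(ids, path)
    tibble::tibble(category = name, n_genes = length(ids), path = path)
  })
  invisible(res)
}
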