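#' Pipeline configuration
#'
#' Collects the tunable thresholds and the seed used by the end-to-end
#' commands. The single `seed` governs every stochastic step (the Kuiper
#' relabeling bootstrap; simulation seeds are part of [sim_config()]).
#'
#' @param period Rhythm period in hours.
#' @param weight_threshold Schwarz-weight threshold for rhythm classes.
#' @param q_cut BH q-value cutoff for difference calls.
#' @param mesor_fc_cut,amp_fc_cut Absolute log2 fold-change filters.
#' @param n_boot Relabelings for the Kuiper bootstrap.
#' @param seed Integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(period = 24, weight_threshold = 0.75,
                            q_cut = 0.05, mesor_fc_cut = 0.25,
                            amp_fc_cut = 0.1, n_boot = 10000, seed = 1L) {
  stopifnot(period > 0, weight_threshold > 0, weight_threshold <= 1,
            q_cut > 0, q_cut <= 1, mesor_fc_cut >= 0, amp_fc_cut >= 0,
            n_boot >= 1)
  structure(
    list(period = period, weight_threshold = weight_threshold, q_cut = q_cut,
         mesor_fc_cut = mesor_fc_cut, amp_fc_cut = amp_fc_cut,
         n_boot = as.integer(n_boot), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

.config_hash <- function(config) rlang::hash(unclass(config))

.run_header <- function(config) {
  paste0("# circadiff ", as.character(utils::packageVersion("circadiff")),
         " seed=", config$seed, " config=", .config_hash(config))
}

#' Run the full transcriptome analysis and write result files
#'
#' Chains the differential cosinor table, the four-model BIC classification,
#' gene categorization, subset export and the heatmap normalization, and
#' writes every table with a header comment carrying the seed and a config
#' hash so reruns are auditable. With identical inputs and configuration the
#' outputs are byte-identical. When a ground-truth table from
#' [simulate_expression()] is supplied, the manifest additionally records
#' the classification accuracy against the planted classes.
#'
#' @param expr Wide expression tibble (`gene_id` + sample columns).
#' @param samples Sample sheet tibble (`sample_id`, `group`, `subject`,
#'   `time_h`).
#' @param out_dir Output directory (created if missing).
#' @param config A [pipeline_config()].
#' @param truth Optional truth tibble with `gene_id` and `class`.
#' @return Invisibly, a list with the computed tables (`diff`, `weights`,
#'   `categories`, `subsets`, `normalized`) and the `manifest`.
#' @export
run_transcriptome <- function(expr, samples, out_dir,
                              config = pipeline_config(), truth = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hdr <- .run_header(config)

  diff <- diff_rhythm_table(expr, samples, period = config$period)
  weights <- classify_matrix(expr, samples,
                             threshold = config$weight_threshold,
                             period = config$period)
  categories <- categorize_genes(diff, weights, q_cut = config$q_cut,
                                 mesor_fc_cut = config$mesor_fc_cut,
                                 amp_fc_cut = config$amp_fc_cut)
  normalized <- heatmap_normalize(expr, samples)
  subsets <- export_subsets(categories, file.path(out_dir, "subsets"))

  .write_table(diff, file.path(out_dir, "diff_rhythm.tsv"), hdr)
  .write_table(weights, file.path(out_dir, "model_weights.tsv"), hdr)
  .write_table(categories, file.path(out_dir, "gene_categories.tsv"), hdr)
  .write_table(
    normalized |>
      tidyr::pivot_wider(id_cols = "gene_id",
                         names_from = c("group", "time_h"),
                         values_from = "value", names_sep = "_t"),
    file.path(out_dir, "heatmap_matrix.tsv"), hdr
  )

  class_counts <- as.list(table(weights$class))
  manifest <- list(
    package = "circadiff",
    version = as.character(utils::packageVersion("circadiff")),
    seed = config$seed,
    config = unclass(config),
    config_hash = .config_hash(config),
    n_genes = nrow(diff),
    n_samples = nrow(samples),
    class_counts = class_counts,
    subset_counts = setNames(as.list(subsets$n_genes), subsets$category)
  )
  if (!is.null(truth)) {
    joined <- dplyr::inner_join(
      weights |> dplyr::select("gene_id", "class"),
      truth |> dplyr::select("gene_id", truth_class = "class"),
      by = "gene_id"
    )
    classified <- joined |> dplyr::filter(.data$class != "unclassified")
    manifest$classification_accuracy <-
      mean(classified$class == classified$truth_class)
    manifest$n_classified <- nrow(classified)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(diff = diff, weights = weights, categories = categories,
                 subsets = subsets, normalized = normalized,
                 manifest = manifest))
}

#' Analyze wearable streams: per-subject cosinor fits and group comparison
#'
#' Fits a fixed-period cosinor to each subject's stream and compares the
#' groups: MESOR and amplitude by the two-sided Wilcoxon rank-sum test
#' (exact when feasible) and peak hour by the two-sample bootstrap Kuiper
#' test, which respects the circular nature of phase.
#'
#' @param wearable Tibble with columns `subject`, `group` ("young"/"old"),
#'   `time_h` and `value` (e.g. from [simulate_wearable()] or
#'   [read_wearable()], possibly after [aggregate_bins()]).
#' @param config A [pipeline_config()]; supplies the period, the Kuiper
#'   `n_boot` and the seed.
#' @param min_hours Subjects whose recording spans fewer hours are excluded
#'   with a warning (default 24).
#' @return List of class `wearable_report`: `fits` (per-subject tibble:
#'   `subject`, `group`, `mesor`, `amplitude`, `peak_hour`, `p_rhythm`) and
#'   `comparison` (tibble: `parameter`, `test`, `statistic`, `p_value`).
#' @export
run_wearable <- function(wearable, config = pipeline_config(),
                         min_hours = 24) {
  stopifnot(inherits(config, "pipeline_config"))
  req <- c("subject", "group", "time_h", "value")
  missing_cols <- setdiff(req, names(wearable))
  if (length(missing_cols)) {
    abort(paste0("`wearable` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  span <- wearable |>
    dplyr::summarise(span = diff(range(.data$time_h)),
                     .by = c("subject", "group"))
  short <- span$subject[span$span < min_hours]
  if (length(short)) {
    warn(paste0("Excluding subject(s) with < ", min_hours,
                " h of data: ", paste(short, collapse = ", ")))
    wearable <- wearable |> dplyr::filter(!.data$subject %in% short)
  }
  if (!nrow(wearable)) abort("No subjects left after exclusions.")

  fits <- wearable |>
    dplyr::group_by(.data$subject, .data$group) |>
    dplyr::group_modify(function(d, key) {
      f <- cosinor_fit(d$time_h, d$value, period = config$period)
      tibble::tibble(mesor = f$mesor, amplitude = f$amplitude,
                     peak_hour = f$peak_hour, p_rhythm = f$p_rhythm,
                     n_obs = f$n_obs)
    }) |>
    dplyr::ungroup()

  yg <- fits |> dplyr::filter(.data$group == "young")
  og <- fits |> dplyr::filter(.data$group == "old")
  if (!nrow(yg) || !nrow(og)) abort("Both groups must be present.")

  rs_m <- ranksum_exact(og$mesor, yg$mesor)
  rs_a <- ranksum_exact(og$amplitude, yg$amplitude)
  ku <- kuiper_two_sample(og$peak_hour, yg$peak_hour,
                          period = config$period, n_boot = config$n_boot,
                          seed = config$seed)
  comparison <- tibble::tibble(
    parameter = c("mesor", "amplitude", "peak_hour"),
    test = c("wilcoxon_rank_sum", "wilcoxon_rank_sum", "kuiper_bootstrap"),
    statistic = c(rs_m$statistic, rs_a$statistic, ku$statistic),
    p_value = c(rs_m$p_value, rs_a$p_value, ku$p_value)
  )
  structure(list(fits = fits, comparison = comparison, config = config),
            class = "wearable_report")
}

#' @export
print.wearable_report <- function(x, ...) {
  cat("Wearable cosinor report:", nrow(x$fits), "subjects\n")
  print(x$comparison)
  invisible(x)
}
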