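#' Configuration for the expression time-course simulator
#'
#' Bundles the parameters of the synthetic two-group serum-synchronization
#' design: two groups ("young", "old") of `subjects_per_group` sera each,
#' sampled every 2 h from 32 to 58 h post synchronization by default, with
#' genes planted as rhythmic in both groups, one group only, or neither.
#' Values live on the log10(1 + normalized count) scale throughout; counts
#' are never materialized.
#'
#' @param n_genes Number of genes to simulate.
#' @param frac_both,frac_young_only,frac_old_only Proportions of genes
#'   rhythmic in both groups, in young only, and in old only; the remainder
#'   is arrhythmic. Must sum to at most 1.
#' @param timepoints Strictly increasing sampling times in hours post
#'   synchronization (default `seq(32, 58, by = 2)`, 14 timepoints).
#' @param subjects_per_group Sera (biological replicates) per group
#'   (default 4).
#' @param period Rhythm period tau in hours (default 24).
#' @param mesor_range,amplitude_range Uniform sampling intervals for the
#'   young-group MESOR and the rhythm amplitude, log10 units.
#' @param mesor_shift_sd SD of the Gaussian old-minus-young MESOR shift
#'   (log10 units, applied to every gene).
#' @param phase_shift_sd SD of the Gaussian old-minus-young peak-hour shift
#'   (hours, applied to genes rhythmic in both groups).
#' @param noise_sd Gaussian measurement noise SD on the log10 scale.
#' @param subject_offset_sd SD of per-gene, per-serum baseline offsets
#'   (log10 units); set to 0 for an iid error model.
#' @param seed Integer seed governing all randomness in the simulation.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000,
                       frac_both = 0.10,
                       frac_young_only = 0.10,
                       frac_old_only = 0.05,
                       timepoints = seq(32, 58, by = 2),
                       subjects_per_group = 4,
                       period = 24,
                       mesor_range = c(1, 3),
                       amplitude_range = c(0.5, 1),
                       mesor_shift_sd = 0.1,
                       phase_shift_sd = 0.5,
                       noise_sd = 0.2,
                       subject_offset_sd = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), frac_both = frac_both,
    frac_young_only = frac_young_only, frac_old_only = frac_old_only,
    timepoints = as.numeric(timepoints),
    subjects_per_group = as.integer(subjects_per_group),
    period = period, mesor_range = mesor_range,
    amplitude_range = amplitude_range, mesor_shift_sd = mesor_shift_sd,
    phase_shift_sd = phase_shift_sd, noise_sd = noise_sd,
    subject_offset_sd = subject_offset_sd, seed = as.integer(seed)
  )
  fracs <- c(cfg$frac_both, cfg$frac_young_only, cfg$frac_old_only)
  if (any(fracs < 0) || any(fracs > 1) || sum(fracs) > 1 + 1e-12) {
    abort("Class proportions must lie in [0,1] and sum to at most 1.")
  }
  if (any(diff(cfg$timepoints) <= 0)) {
    abort("`timepoints` must be strictly increasing.")
  }
  if (length(cfg$timepoints) < 4) {
    abort("At least 4 timepoints are required (the cosinor fit is underdetermined below that).")
  }
  if (cfg$noise_sd < 0 || cfg$subject_offset_sd < 0 ||
      cfg$mesor_shift_sd < 0 || cfg$phase_shift_sd < 0) {
    abort("Standard deviations must be non-negative.")
  }
  if (cfg$n_genes < 1 || cfg$subjects_per_group < 1) {
    abort("`n_genes` and `subjects_per_group` must be positive.")
  }
  structure(cfg, class = "sim_config")
}

# deterministic class assignment by gene index: first ceil(frac_both * n)
# genes are "both", then young_only, then old_only, remainder "neither".
# Stable across seeds; randomness only affects parameters and noise.
.assign_classes <- function(cfg) {
  n <- cfg$n_genes
  n_both <- ceiling(cfg$frac_both * n)
  n_yo <- ceiling(cfg$frac_young_only * n)
  n_oo <- ceiling(cfg$frac_old_only * n)
  if (n_both + n_yo + n_oo > n) {
    abort("Class counts exceed `n_genes`; reduce the class proportions.")
  }
  rep(c("both", "young_only", "old_only", "neither"),
      c(n_both, n_yo, n_oo, n - n_both - n_yo - n_oo))
}

#' Simulate a two-group expression time course with planted rhythms
#'
#' Generates a gene-by-sample matrix on the log10(1 + normalized count)
#' scale following the cosinor model
#' `y = M_g + b_s + A_g * cos(2 * pi * (t - t_peak_g) / period) + e`,
#' with per-serum baseline offsets `b_s ~ N(0, subject_offset_sd^2)` and
#' noise `e ~ N(0, noise_sd^2)`, together with the ground-truth parameter
#' table. Gene classes (rhythmic in both groups / young only / old only /
#' neither) are assigned deterministically by gene index so truth tables are
#' stable across seeds.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `expr_sim` with elements
#'   \describe{
#'     \item{expression}{tibble, `gene_id` plus one column per sample.}
#'     \item{samples}{tibble: `sample_id`, `group`, `subject`, `time_h`.}
#'     \item{truth}{tibble: `gene_id`, `class`, per-group MESOR, amplitude
#'       and peak hour (`amp = 0` for groups where the gene is arrhythmic).}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 50, seed = 7))
#' dim(sim$expression)
#' @export
simulate_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n <- cfg$n_genes
  cls <- .assign_classes(cfg)
  tau <- cfg$period
  groups <- c("young", "old")
  subj <- LETTERS[seq_len(cfg$subjects_per_group)]

  samples <- tidyr::expand_grid(
    group = groups, subject = subj, time_h = cfg$timepoints
  ) |>
    dplyr::mutate(sample_id = paste0(.data$group, "_", .data$subject, "_t",
                                     .data$time_h),
                  .before = 1)

  out <- withr::with_seed(cfg$seed, {
    mesor_y <- runif(n, cfg$mesor_range[1], cfg$mesor_range[2])
    mesor_o <- mesor_y + rnorm(n, 0, cfg$mesor_shift_sd)
    amp <- runif(n, cfg$amplitude_range[1], cfg$amplitude_range[2])
    peak_y <- runif(n, 0, tau)
    peak_o <- (peak_y + rnorm(n, 0, cfg$phase_shift_sd)) %% tau

    amp_y <- ifelse(cls %in% c("both", "young_only"), amp, 0)
    amp_o <- ifelse(cls %in% c("both", "old_only"), amp, 0)
    # arrhythmic groups keep the drawn peak (irrelevant when amplitude = 0)
    # so the truth table is complete and NA-free
    peak_y_out <- peak_y
    peak_o_out <- ifelse(cls == "both", peak_o, peak_y)

    # per-gene x per-(group,subject) baseline offsets
    n_subj_tot <- 2 * cfg$subjects_per_group
    b <- matrix(rnorm(n * n_subj_tot, 0, cfg$subject_offset_sd), n, n_subj_tot)
    subj_key <- paste(rep(groups, each = cfg$subjects_per_group),
                      rep(subj, 2), sep = "_")
    colnames(b) <- subj_key

    w <- 2 * pi / tau
    mat <- matrix(NA_real_, n, nrow(samples))
    for (j in seq_len(nrow(samples))) {
      g <- samples$group[j]
      mg <- if (g == "young") mesor_y else mesor_o
      ag <- if (g == "young") amp_y else amp_o
      pg <- if (g == "young") peak_y else ifelse(cls == "both", peak_o, peak_y)
      bj <- b[, paste(g, samples$subject[j], sep = "_")]
      mat[, j] <- mg + bj + ag * cos(w * (samples$time_h[j] - pg))
    }
    mat <- mat + matrix(rnorm(length(mat), 0, cfg$noise_sd), nrow(mat))

    list(mat = mat,
         truth = tibble::tibble(
           gene_id = sprintf("gene_%05d", seq_len(n)),
           class = cls,
           mesor_young = mesor_y, mesor_old = mesor_o,
           amp_young = amp_y, amp_old = amp_o,
           peak_young = peak_y_out, peak_old = peak_o_out
         ))
  })

  mat <- out$mat
  dimnames(mat) <- list(out$truth$gene_id, samples$sample_id)
  structure(
    list(
      expression = dplyr::bind_cols(
        tibble::tibble(gene_id = out$truth$gene_id),
        tibble::as_tibble(mat)
      ),
      samples = samples,
      truth = out$truth,
      config = cfg
    ),
    class = "expr_sim"
  )
}

#' @export
print.expr_sim <- function(x, ...) {
  cat("Simulated expression time course:",
      nrow(x$expression), "genes x", nrow(x$samples), "samples\n")
  cat("Classes:", paste(sprintf("%s=%d", names(table(x$truth$class)),
                                table(x$truth$class)), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate wearable-device time series for two groups
#'
#' Generates regular binned streams (one value per subject per bin, at bin
#' midpoints) following a 24-h cosine with group-level MESOR, amplitude and
#' peak hour, per-subject level and phase jitter, and Gaussian noise. A
#' stand-in for actigraphy counts or heart-rate series used to exercise the
#' wearable analysis end to end.
#'
#' @param n_subjects_per_group Subjects per group (default 8).
#' @param days Recording length in days (>= 1).
#' @param bin_minutes Bin width in minutes; must divide 60.
#' @param mesor,amplitude,peak_hour Named numeric vectors with elements
#'   `young` and `old` giving the group-level cosinor parameters.
#' @param noise_sd Within-subject noise SD.
#' @param level_jitter_sd,phase_jitter_sd Per-subject random shifts of the
#'   MESOR (value units) and peak hour (hours).
#' @param period Period in hours (default 24).
#' @param seed Integer seed.
#' @return Tibble: `subject`, `group`, `time_h`, `value`.
#' @export
simulate_wearable <- function(n_subjects_per_group = 8,
                              days = 7,
                              bin_minutes = 60,
                              mesor = c(young = 2000, old = 1800),
                              amplitude = c(young = 1500, old = 1400),
                              peak_hour = c(young = 15, old = 13.5),
                              noise_sd = 300,
                              level_jitter_sd = 100,
                              phase_jitter_sd = 1,
                              period = 24,
                              seed = 1L) {
  if (n_subjects_per_group < 1 || days < 1 || bin_minutes < 1) {
    abort("`n_subjects_per_group`, `days` and `bin_minutes` must be positive.")
  }
  if (60 %% bin_minutes != 0) {
    abort("`bin_minutes` must divide 60.")
  }
  groups <- c("young", "old")
  stopifnot(all(groups %in% names(mesor)), all(groups %in% names(amplitude)),
            all(groups %in% names(peak_hour)))
  n_bins <- days * 24 * 60 / bin_minutes
  time_h <- (seq_len(n_bins) - 0.5) * bin_minutes / 60
  w <- 2 * pi / period

  withr::with_seed(seed, {
    purrr::map_dfr(groups, function(g) {
      purrr::map_dfr(seq_len(n_subjects_per_group), function(s) {
        lev <- mesor[[g]] + rnorm(1, 0, level_jitter_sd)
        pk <- peak_hour[[g]] + rnorm(1, 0, phase_jitter_sd)
        val <- lev + amplitude[[g]] * cos(w * (time_h - pk)) +
          rnorm(n_bins, 0, noise_sd)
        tibble::tibble(
          subject = sprintf("%s_%02d", g, s),
          group = g, time_h = time_h, value = val
        )
      })
    })
  })
}
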