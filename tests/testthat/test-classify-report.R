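# minimal hand-built diff/weights rows covering the categorization rules
fake_tables <- function() {
  diff <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4", "g5"),
    mesor_diff = c(0.3, -0.2, 0, 0.01, 0.5),
    amp_young = c(0.5, 0.4, 0.5, 0.5, 0.6),
    amp_old = c(0.5, 0.2, 0.5, 0.5, 0.6),
    amp_diff = c(0, -0.2, 0, 0, 0),
    phase_diff = c(1.2, -3, 0.5, 0.2, 0),
    q_mesor_diff = c(0.2, 0.01, 0.5, 0.9, 0.001),
    q_amp_diff = c(0.5, 0.02, 0.5, 0.9, 0.6),
    q_phase_diff = c(0.01, 0.03, 0.5, 0.9, 0.7)
  )
  weights <- tibble::tibble(
    gene_id = diff$gene_id,
    class = c("both", "both", "young_only", "both", "old_only")
  )
  list(diff = diff, weights = weights)
}

test_that("categorization applies the q, sign and class rules", {
  ft <- fake_tables()
  rec <- categorize_genes(ft$diff, ft$weights)
  rec <- rec[match(ft$diff$gene_id, rec$gene_id), ]
  # g1: both, significant positive phase diff -> delay; no mesor/amp call
  expect_equal(rec$phase_change[1], "delay")
  expect_equal(rec$mesor_change[1], "none")
  # g2: both, mesor down, amp down, phase advance
  expect_equal(rec$mesor_change[2], "down")
  expect_equal(rec$amp_change[2], "down")
  expect_equal(rec$phase_change[2], "advance")
  # g3: young_only -> loss; change fields forced to none
  expect_equal(rec$rhythm_class[3], "young_only")
  expect_true(all(c(rec$mesor_change[3], rec$amp_change[3],
                    rec$phase_change[3]) == "none"))
  # g4: both but all q above cutoff -> all none
  expect_true(all(c(rec$mesor_change[4], rec$amp_change[4],
                    rec$phase_change[4]) == "none"))
  # g5: old_only (gain); significant mesor q is ignored outside class both
  expect_equal(rec$mesor_change[5], "none")

  # fold-change conventions
  expect_equal(rec$mesor_log2fc, ft$diff$mesor_diff * log2(10))
  expect_equal(rec$amp_log2fc[2], log2(0.2 / 0.4))
  expect_true(rec$passes_mesor_fc_filter[2])   # |(-0.2)*log2(10)| > 0.25
  expect_true(rec$passes_amp_fc_filter[2])     # |log2(0.5)| = 1 > 0.1
})

test_that("raising the q cutoff never shrinks the change sets", {
  ft <- fake_tables()
  lo <- categorize_genes(ft$diff, ft$weights, q_cut = 0.02)
  hi <- categorize_genes(ft$diff, ft$weights, q_cut = 0.10)
  for (fld in c("mesor_change", "amp_change", "phase_change")) {
    called_lo <- lo$gene_id[lo[[fld]] != "none"]
    called_hi <- hi$gene_id[hi[[fld]] != "none"]
    expect_true(all(called_lo %in% called_hi))
  }
})

test_that("rhythm classes partition the gene universe", {
  sim <- simulate_expression(sim_config(n_genes = 100, seed = 71))
  d <- diff_rhythm_table(sim$expression, sim$samples)
  w <- classify_matrix(sim$expression, sim$samples)
  rec <- categorize_genes(d, w)
  expect_setequal(rec$gene_id, sim$truth$gene_id)
  expect_true(all(rec$rhythm_class %in%
                    c("both", "neither", "young_only", "old_only",
                      "unclassified")))
  filt <- circadiff:::.subset_filters(rec)
  # loss/gain/both are mutually exclusive
  expect_true(all(filt$rhythmic_both + filt$loss_of_rhythmicity +
                    filt$gain_of_rhythmicity <= 1))
})

test_that("three-round heatmap normalization meets its postconditions", {
  sim <- simulate_expression(sim_config(n_genes = 25, seed = 72))
  hm <- heatmap_normalize(sim$expression, sim$samples)
  stats <- hm |>
    dplyr::summarise(m = mean(value), s = sd(value),
                     flagged = any(flagged),
                     .by = c(gene_id, group))
  ok <- !stats$flagged
  expect_true(any(ok))
  expect_true(all(abs(stats$m[ok]) < 1e-12))
  expect_true(all(abs(stats$s[ok] - 1) < 1e-12))

  # idempotence of the z-scoring round
  rez <- hm |>
    dplyr::mutate(value2 = (value - mean(value)) / sd(value),
                  .by = c(gene_id, group))
  expect_equal(rez$value2[!rez$flagged], rez$value[!rez$flagged],
               tolerance = 1e-10)
})

test_that("constant genes come out flagged and all-zero", {
  pars <- tibble::tibble(mesor = c(2, 3), amp = c(0.5, 0), peak = c(4, 0))
  d <- make_two_group_matrix(pars, pars, noise_sd = 0)
  hm <- heatmap_normalize(d$expr, d$samples)
  g2 <- hm[hm$gene_id == "g002", ]
  expect_true(all(g2$flagged))
  expect_true(all(g2$value == 0))
})

test_that("the hand-computed two-gene fixture is reproduced exactly", {
  # one group, two sera, three timepoints:
  # g1 subject A: (1,2,3) /mean 2 -> (.5,1,1.5); subject B: (2,4,6)/4 -> same
  # collapse -> (.5,1,1.5); z -> (-1,0,1)
  # g2 constant 5 -> (1,1,1) -> sd 0 -> flagged zeros
  samples <- tibble::tibble(
    sample_id = c("yA1", "yA2", "yA3", "yB1", "yB2", "yB3"),
    group = "young", subject = rep(c("A", "B"), each = 3),
    time_h = rep(c(1, 2, 3), 2)
  )
  expr <- tibble::tibble(
    gene_id = c("g1", "g2"),
    yA1 = c(1, 5), yA2 = c(2, 5), yA3 = c(3, 5),
    yB1 = c(2, 5), yB2 = c(4, 5), yB3 = c(6, 5)
  )
  hm <- heatmap_normalize(expr, samples)
  g1 <- hm[hm$gene_id == "g1", ]
  expect_equal(g1$value, c(-1, 0, 1))
  expect_false(any(g1$flagged))
  g2 <- hm[hm$gene_id == "g2", ]
  expect_equal(g2$value, c(0, 0, 0))
  expect_true(all(g2$flagged))
})

test_that("subset export writes seven lists matching an independent filter", {
  tmp <- withr::local_tempdir()
  # empty records -> seven empty files
  ft <- fake_tables()
  rec <- categorize_genes(ft$diff, ft$weights)
  empty <- export_subsets(rec[0, ], file.path(tmp, "empty"))
  expect_equal(nrow(empty), 7)
  expect_true(all(empty$n_genes == 0))
  expect_true(all(file.exists(empty$path)))

  sim <- simulate_expression(sim_config(n_genes = 200, seed = 73))
  d <- diff_rhythm_table(sim$expression, sim$samples)
  w <- classify_matrix(sim$expression, sim$samples)
  rec2 <- categorize_genes(d, w)
  res <- export_subsets(rec2, file.path(tmp, "subsets"))
  expect_setequal(res$category,
                  c("rhythmic_both", "loss_of_rhythmicity",
                    "gain_of_rhythmicity", "mesor_decrease",
                    "mesor_increase", "phase_advance", "phase_delay"))
  # second-pass re-implementation of the filters
  expected <- c(
    rhythmic_both = sum(rec2$rhythm_class == "both"),
    loss_of_rhythmicity = sum(rec2$rhythm_class == "young_only"),
    gain_of_rhythmicity = sum(rec2$rhythm_class == "old_only"),
    mesor_decrease = sum(rec2$mesor_change == "down"),
    mesor_increase = sum(rec2$mesor_change == "up"),
    phase_advance = sum(rec2$phase_change == "advance"),
    phase_delay = sum(rec2$phase_change == "delay")
  )
  got <- setNames(res$n_genes, res$category)
  expect_equal(got[names(expected)], expected)
  for (p in res$path) {
    ids <- readLines(p)
    expect_equal(anyDuplicated(ids), 0)
  }
})
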