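#' Read an expression matrix from TSV
#'
#' Expects genes in rows with the gene identifier in the first column and
#' one column per sample. Lines starting with `#` are treated as comments.
#'
#' @param path Path to a TSV file.
#' @return Wide tibble with a `gene_id` first column.
#' @export
read_expression_matrix <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  names(df)[1] <- "gene_id"
  df
}

#' Read a sample sheet from CSV
#'
#' @param path Path to a CSV with columns `sample_id`, `group`, `subject`,
#'   `time_h` (comment lines start with `#`).
#' @return Tibble.
#' @export
read_sample_sheet <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Read a wearable stream from CSV
#'
#' @param path Path to a CSV with columns `subject`, `group`, `time_h`
#'   (hours since an arbitrary origin) and `value`.
#' @return Tibble.
#' @export
read_wearable <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Write a simulated expression bundle to disk
#'
#' Writes the expression matrix as TSV (first column `gene_id`), the sample
#' sheet and the ground-truth table as CSV.
#'
#' @param sim Output of [simulate_expression()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_expression_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "expr_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    samples = file.path(dir, "samples.csv"),
    truth = file.path(dir, "truth.csv")
  )
  readr::write_tsv(sim$expression, paths[["expression"]])
  readr::write_csv(sim$samples, paths[["samples"]])
  readr::write_csv(sim$truth, paths[["truth"]])
  invisible(paths)
}

# write a table as TSV with a reproducibility header comment
.write_table <- function(df, path, header) {
  writeLines(header, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
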