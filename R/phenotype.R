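#' Correlation matrix between molecular measures and phenotypes
#'
#' Pearson correlation of every (measure, phenotype) pair over
#' pairwise-complete samples, with the per-cell sample size. Cells with
#' fewer than `min_n` complete pairs are reported as missing. No
#' multiple-testing correction is applied (raw r and p are reported, as
#' is conventional for small phenotype panels); the `adjusted` attribute
#' records this.
#'
#' @param measures A data frame with `sample_id` and one numeric column
#'   per molecular measure (e.g. methylation metrics, fold changes).
#' @param phenotypes A data frame with `sample_id` and one numeric
#'   column per phenotype score (e.g. clinical interview domains, neuron
#'   density).
#' @param min_n Minimum pairwise-complete sample count per cell.
#' @return An `assoc_matrix`: a long tibble `measure`, `phenotype`, `r`,
#'   `p`, `n`.
#' @export
assoc_matrix <- function(measures, phenotypes, min_n = 3) {
  measures <- as_tibble(measures)
  phenotypes <- as_tibble(phenotypes)
  check_that("sample_id" %in% names(measures) &&
               "sample_id" %in% names(phenotypes),
             "both tables need a sample_id column")
  shared <- intersect(measures$sample_id, phenotypes$sample_id)
  if (length(shared) == 0) abort("no overlapping samples")
  m <- measures[match(shared, measures$sample_id), , drop = FALSE]
  p <- phenotypes[match(shared, phenotypes$sample_id), , drop = FALSE]
  mcols <- setdiff(names(m), "sample_id")
  pcols <- setdiff(names(p), "sample_id")
  out <- tidyr::expand_grid(measure = mcols, phenotype = pcols) |>
    mutate(cell = map2(.data$measure, .data$phenotype, function(mc, pc) {
      x <- m[[mc]]; y <- p[[pc]]
      res <- pearson_test(x, y)
      if (res$n < min_n) res[c("r", "p")] <- NA_real_
      res
    })) |>
    tidyr::unnest("cell")
  attr(out, "adjusted") <- FALSE
  class(out) <- c("assoc_matrix", class(out))
  out
}

#' Compare neuron density between groups
#'
#' Thin wrapper around [group_compare()] for cell-density measurements
#' (counts per unit area) in case versus control tissue.
#'
#' @param density_case,density_ctrl Numeric vectors of per-sample
#'   densities (length >= 2 each).
#' @return A one-row tibble as returned by [group_compare()].
#' @export
density_compare <- function(density_case, density_ctrl) {
  group_compare(density_case, density_ctrl)
}
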