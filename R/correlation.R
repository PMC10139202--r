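#' Median-of-ratios size factors
#'
#' Per-sample normalization factors by the geometric-mean (median-of-
#' ratios) method: the reference for feature *i* is its geometric mean
#' across samples, computed over features with all-positive counts, and
#' the factor for sample *j* is the median over those features of
#' `count[i, j] / geomean[i]`.
#'
#' @param counts A non-negative count matrix (features x samples).
#' @return A named numeric vector of positive size factors, one per
#'   sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  ok <- rowSums(counts <= 0) == 0
  if (!any(ok)) {
    abort(paste("no feature with all-positive counts; consider a",
                "pseudo-reference (e.g. counts + 1)"))
  }
  logc <- log(counts[ok, , drop = FALSE])
  logratio <- logc - rowMeans(logc)
  sf <- exp(apply(logratio, 2, median))
  setNames(sf, colnames(counts))
}

#' Log-scale normalized expression
#'
#' `log2(count / size_factor + pseudocount)`. A variance-stabilized
#' transform in the spirit of regularized-log values but without
#' shrinkage; adequate for Pearson correlation screening at these sample
#' sizes.
#'
#' @param counts Count matrix (features x samples).
#' @param factors Positive per-sample size factors (default:
#'   [size_factors()]).
#' @param pseudocount Added before the log (default 1, so a zero count
#'   maps to 0).
#' @return A numeric matrix of the same shape.
#' @export
normalize_log <- function(counts, factors = size_factors(counts),
                          pseudocount = 1) {
  check_that(all(factors > 0), "size factors must be positive")
  counts <- as.matrix(counts)
  log2(sweep(counts, 2, factors, "/") + pseudocount)
}

#' Family composition of differentially expressed TEs
#'
#' For each repeat family: the number of DE elements, its share of all DE
#' elements, and the rate of DE elements within the family (DE count over
#' the family's total genomic element count) - the comparison that
#' distinguishes genuinely enriched families from merely abundant ones.
#'
#' @param de A tibble of DE records with columns `feature_id`, `family`
#'   and (for directional filters) `log2fc`.
#' @param family_totals Named numeric vector or two-column data frame
#'   (`family`, `total`) of total element counts per family.
#' @param direction `"all"`, `"up"` (log2fc > 0) or `"down"` (log2fc < 0).
#' @return A tibble `family`, `n_de`, `share_of_de`, `rate_in_family`.
#' @export
family_distribution <- function(de, family_totals,
                                direction = c("all", "up", "down")) {
  direction <- match.arg(direction)
  de <- as_tibble(de)
  if (is.data.frame(family_totals)) {
    family_totals <- setNames(family_totals$total, family_totals$family)
  }
  de <- switch(direction,
               all = de,
               up = filter(de, .data$log2fc > 0),
               down = filter(de, .data$log2fc < 0))
  unknown <- setdiff(unique(de$family), names(family_totals))
  if (length(unknown) > 0) {
    abort(paste0("family missing from totals: ",
                 paste(unknown, collapse = ", ")))
  }
  de |>
    count(.data$family, name = "n_de") |>
    mutate(share_of_de = .data$n_de / sum(.data$n_de),
           rate_in_family = .data$n_de / unname(family_totals[.data$family]))
}

#' Pearson correlation with a two-sided t test
#'
#' Product-moment correlation with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Zero-variance input yields an undefined correlation, returned as `NA`
#' so callers can exclude it from multiple-testing families.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return A one-row tibble `r`, `p`, `n`.
#' @export
pearson_test <- function(x, y) {
  check_that(length(x) == length(y), "x and y must have equal length")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3 || sd(x) == 0 || sd(y) == 0) {
    return(tibble(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "pearson"))
  tibble(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone in rank, capped at 1). Missing values
#' are preserved and excluded from the family size.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  check_that(all(is.na(p) | (p >= 0 & p <= 1)), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Upper-tail hypergeometric enrichment probability
#'
#' `P(X >= k)` where `X` is the overlap between a list of size `n` and a
#' panel of size `K` drawn without replacement from a background of size
#' `N`. Computed with the hypergeometric upper tail (log-space internals
#' of the distribution function keep small probabilities accurate).
#'
#' @param overlap_k Observed overlap.
#' @param list_n Size of the query list.
#' @param set_K Size of the annotated panel.
#' @param background_N Size of the background universe.
#' @return A single upper-tail probability.
#' @export
enrichment_hypergeom <- function(overlap_k, list_n, set_K, background_N) {
  ok <- overlap_k >= 0 && list_n >= 0 && set_K >= 0 &&
    overlap_k <= min(list_n, set_K) && list_n <= background_N &&
    set_K <= background_N
  if (!ok) abort("inconsistent counts: need 0 <= k <= min(n, K) <= N")
  exp(phyper(overlap_k - 1, set_K, background_N - set_K, list_n,
             lower.tail = FALSE, log.p = TRUE))
}

# Row-wise Pearson r and two-sided p for paired rows of two matrices
# (same number of rows; columns are samples).
paired_row_cor <- function(a, b) {
  n <- ncol(a)
  ca <- a - rowMeans(a)
  cb <- b - rowMeans(b)
  sa <- sqrt(rowSums(ca^2))
  sb <- sqrt(rowSums(cb^2))
  r <- rowSums(ca * cb) / (sa * sb)
  r[sa == 0 | sb == 0] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(r = r, p = p, n = n)
}

#' Cis-regulation correlation screen
#'
#' For every assigned (TE, gene) pair, Pearson correlation of normalized
#' expression computed three times - across all samples, controls only
#' and cases only - with Benjamini-Hochberg adjustment applied separately
#' within each of the three families across all tested pairs.
#' Zero-variance pairs are excluded from the family. Groups smaller than
#' `min_n` yield missing values for that group.
#'
#' @param te_expr,gene_expr Normalized expression matrices (features x
#'   samples, same sample order; see [normalize_log()]).
#' @param assignments Tibble with `te_id`, `gene_id` (and optionally
#'   `classes`) naming the pairs to test, e.g. from [assign_features()].
#' @param samples A sample table; `sample_id` order must match the
#'   expression columns.
#' @param fdr Significance threshold on adjusted p (default 0.05).
#' @param min_n Minimum per-group sample size (default 3).
#' @return A `te_correlation` object; `tidy()` returns the per-pair
#'   records (`r_all`, `p_all`, `padj_all`, `sig_all`, and the `_ctrl`,
#'   `_case` counterparts), `glance()` the per-group significant counts.
#' @export
cis_correlate <- function(te_expr, gene_expr, assignments, samples,
                          fdr = 0.05, min_n = 3) {
  samples <- sample_table(samples)
  check_that(ncol(te_expr) == nrow(samples) &&
               ncol(gene_expr) == nrow(samples),
             "expression matrices and sample table disagree on sample count")
  assignments <- as_tibble(assignments)
  known <- assignments$te_id %in% rownames(te_expr) &
    assignments$gene_id %in% rownames(gene_expr)
  if (any(!known)) {
    warn(sprintf("skipping %d pair(s) referencing missing features",
                 sum(!known)))
    assignments <- assignments[known, , drop = FALSE]
  }
  a <- te_expr[assignments$te_id, , drop = FALSE]
  b <- gene_expr[assignments$gene_id, , drop = FALSE]
  groups <- list(all = rep(TRUE, nrow(samples)),
                 ctrl = samples$group == "control",
                 case = samples$group == "case")
  rec <- assignments
  for (g in names(groups)) {
    idx <- groups[[g]]
    if (sum(idx) >= max(min_n, 3)) {
      cr <- paired_row_cor(a[, idx, drop = FALSE], b[, idx, drop = FALSE])
    } else {
      cr <- list(r = rep(NA_real_, nrow(a)), p = rep(NA_real_, nrow(a)),
                 n = sum(idx))
    }
    rec[[paste0("n_", g)]] <- cr$n
    rec[[paste0("r_", g)]] <- cr$r
    rec[[paste0("p_", g)]] <- cr$p
    rec[[paste0("padj_", g)]] <- bh_adjust(cr$p)
    rec[[paste0("sig_", g)]] <- !is.na(rec[[paste0("padj_", g)]]) &
      rec[[paste0("padj_", g)]] < fdr
  }
  structure(list(records = rec, mode = "cis", fdr = fdr),
            class = "te_correlation")
}

#' Trans-regulation correlation screen
#'
#' Enumerates all DE-TE x DE-gene pairs, computes Pearson r and p per
#' group (all, control, case), applies Benjamini-Hochberg over the full
#' pair family within each group, and reports the TE elements appearing
#' in at least one significant pair per group together with their overlap
#' algebra (see [trans_overlap()]).
#'
#' @inheritParams cis_correlate
#' @return A `te_correlation` object with mode `"trans"`; the `overlap`
#'   element holds the case/control TE element sets and their overlap.
#' @export
trans_correlate <- function(te_expr, gene_expr, samples, fdr = 0.05,
                            min_n = 3) {
  samples <- sample_table(samples)
  groups <- list(all = rep(TRUE, nrow(samples)),
                 ctrl = samples$group == "control",
                 case = samples$group == "case")
  rec <- tidyr::expand_grid(te_id = rownames(te_expr),
                            gene_id = rownames(gene_expr))
  for (g in names(groups)) {
    idx <- groups[[g]]
    n <- sum(idx)
    if (n >= max(min_n, 3)) {
      r <- cor(t(te_expr[, idx, drop = FALSE]),
               t(gene_expr[, idx, drop = FALSE]))
      sds_te <- apply(te_expr[, idx, drop = FALSE], 1, sd)
      sds_gene <- apply(gene_expr[, idx, drop = FALSE], 1, sd)
      r[sds_te == 0, ] <- NA_real_
      r[, sds_gene == 0] <- NA_real_
      rv <- as.vector(t(r))  # row-major to match expand_grid order
      tstat <- rv * sqrt((n - 2) / pmax(1 - rv^2, .Machine$double.eps))
      pv <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    } else {
      rv <- rep(NA_real_, nrow(rec)); pv <- rv
    }
    rec[[paste0("n_", g)]] <- n
    rec[[paste0("r_", g)]] <- rv
    rec[[paste0("p_", g)]] <- pv
    rec[[paste0("padj_", g)]] <- bh_adjust(pv)
    rec[[paste0("sig_", g)]] <- !is.na(rec[[paste0("padj_", g)]]) &
      rec[[paste0("padj_", g)]] < fdr
  }
  ov <- trans_overlap(unique(rec$te_id[rec$sig_case]),
                      unique(rec$te_id[rec$sig_ctrl]))
  structure(list(records = rec, mode = "trans", fdr = fdr, overlap = ov),
            class = "te_correlation")
}

#' Overlap algebra of case/control element sets
#'
#' Splits two element-id sets into shared and exclusive parts. The
#' cardinalities always satisfy `|shared| + |only_case| = |case|` and
#' `|shared| + |only_ctrl| = |ctrl|`.
#'
#' @param set_case,set_ctrl Character vectors of element ids (duplicates
#'   are dropped).
#' @return A `trans_overlap` object (a list with `set_case`, `set_ctrl`,
#'   `shared`, `only_case`, `only_ctrl`); `glance()` gives the counts.
#' @export
trans_overlap <- function(set_case, set_ctrl) {
  set_case <- unique(set_case); set_ctrl <- unique(set_ctrl)
  structure(list(set_case = set_case, set_ctrl = set_ctrl,
                 shared = intersect(set_case, set_ctrl),
                 only_case = setdiff(set_case, set_ctrl),
                 only_ctrl = setdiff(set_ctrl, set_case)),
            class = "trans_overlap")
}

#' @export
glance.trans_overlap <- function(x, ...) {
  tibble(n_case = length(x$set_case), n_ctrl = length(x$set_ctrl),
         n_shared = length(x$shared), n_only_case = length(x$only_case),
         n_only_ctrl = length(x$only_ctrl))
}

#' @export
print.trans_overlap <- function(x, ...) {
  cat("<trans_overlap>\n")
  print(glance(x))
  invisible(x)
}

#' @export
tidy.te_correlation <- function(x, ...) {
  x$records
}

#' @export
glance.te_correlation <- function(x, ...) {
  r <- x$records
  tibble(mode = x$mode, fdr = x$fdr, n_pairs = nrow(r),
         n_sig_all = sum(r$sig_all, na.rm = TRUE),
         n_sig_ctrl = sum(r$sig_ctrl, na.rm = TRUE),
         n_sig_case = sum(r$sig_case, na.rm = TRUE),
         n_te_sig_case = n_distinct(r$te_id[r$sig_case]),
         n_te_sig_ctrl = n_distinct(r$te_id[r$sig_ctrl]))
}

#' @export
print.te_correlation <- function(x, ...) {
  cat(sprintf("<te_correlation> mode = %s, FDR = %g\n", x$mode, x$fdr))
  print(glance(x))
  invisible(x)
}

#' Filter a DE table to the significance thresholds
#'
#' DE calling itself (negative-binomial modelling, unwanted-variation
#' removal) is consumed as input, not recomputed; this applies the
#' adjusted-p and fold-change thresholds used to define DE features.
#'
#' @param de Tibble with `feature_id`, `log2fc`, `pvalue`, `padj` and
#'   optionally `family`, `subfamily`.
#' @param padj_max Adjusted-p threshold (default 0.01).
#' @param lfc_min Minimum `|log2fc|` (default 1).
#' @return The filtered tibble.
#' @export
filter_de <- function(de, padj_max = 0.01, lfc_min = 1) {
  de <- as_tibble(de)
  check_that(all(de$pvalue >= 0 & de$pvalue <= 1, na.rm = TRUE) &&
               all(de$padj >= 0 & de$padj <= 1, na.rm = TRUE),
             "p-values must lie in [0, 1]")
  filter(de, .data$padj < padj_max, abs(.data$log2fc) > lfc_min)
}
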