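#' COBRA methylation level and patterns from gel band intensities
#'
#' Converts the six COBRA band intensities A-F of a two-CpG assay into
#' the methylation level and the four pattern percentages:
#' \deqn{\%mC = 100 (E + B) / (2A + E + B + C + D)}
#' \deqn{\%mCmC = 100 F / (A + C + D + F)}
#' \deqn{\%uCmC = 100 C / (A + C + D + F)}
#' \deqn{\%mCuC = 100 D / (A + C + D + F)}
#' \deqn{\%uCuC = 100 A / (A + C + D + F)}
#' The roles implied by the formulas: `A` is the fully unmethylated
#' pattern band, `F` the fully methylated pattern band, `C`/`D` the two
#' partially methylated pattern bands, and `B`/`E` methylated-site
#' fragment bands. The four pattern percentages sum to 100 by
#' construction, and all percentages are invariant to rescaling all six
#' bands.
#'
#' @param bands A data frame with numeric columns `A`-`F` (one row per
#'   sample/assay/replicate; any other columns are carried through).
#' @return The input tibble with `pct_mC`, `pct_mCmC`, `pct_uCmC`,
#'   `pct_mCuC`, `pct_uCuC` appended.
#' @export
cobra_percentages <- function(bands) {
  bands <- as_tibble(bands)
  check_that(all(c("A", "B", "C", "D", "E", "F") %in% names(bands)),
             "band table needs columns A, B, C, D, E, F")
  with(bands, {
    check_that(all(c(A, B, C, D, E, F) >= 0), "band intensities must be >= 0")
  })
  denom_level <- with(bands, 2 * A + E + B + C + D)
  denom_pattern <- with(bands, A + C + D + F)
  if (any(denom_level <= 0)) {
    abort("zero denominator in %mC formula (2A + E + B + C + D)")
  }
  if (any(denom_pattern <= 0)) {
    abort("zero denominator in pattern formulas (A + C + D + F)")
  }
  bands |>
    mutate(pct_mC = 100 * (.data$E + .data$B) / denom_level,
           pct_mCmC = 100 * .data$F / denom_pattern,
           pct_uCmC = 100 * .data$C / denom_pattern,
           pct_mCuC = 100 * .data$D / denom_pattern,
           pct_uCuC = 100 * .data$A / denom_pattern)
}

PCT_COLS <- c("pct_mC", "pct_mCmC", "pct_uCmC", "pct_mCuC", "pct_uCuC")
PATTERN_COLS <- c("pct_mCmC", "pct_uCmC", "pct_mCuC", "pct_uCuC")

#' Interassay normalization against a control cell line
#'
#' Each metric of a sample profile is multiplied by the ratio of the
#' reference control profile to the batch's own measurement of the same
#' control (ratio-to-reference scaling), after which the four pattern
#' percentages are renormalized to sum to 100.
#'
#' @param profile A tibble of methylation profiles (columns `pct_*`, see
#'   [cobra_percentages()]).
#' @param batch_control_profile,reference_control_profile One-row
#'   profiles of the control line measured in this batch and in the
#'   reference batch.
#' @return `profile` with metrics rescaled.
#' @export
interassay_normalize <- function(profile, batch_control_profile,
                                 reference_control_profile) {
  for (col in PCT_COLS) {
    b <- batch_control_profile[[col]][1]
    r <- reference_control_profile[[col]][1]
    if (is.null(b) || is.na(b) || b == 0) {
      abort(sprintf("batch control metric %s is zero or missing", col))
    }
    profile[[col]] <- profile[[col]] * (r / b)
  }
  pat_sum <- rowSums(as.matrix(profile[PATTERN_COLS]))
  for (col in PATTERN_COLS) {
    profile[[col]] <- 100 * profile[[col]] / pat_sum
  }
  profile
}

#' Average technical replicates of methylation profiles
#'
#' Profiles measured in duplicate are averaged per sample and assay;
#' replicate pairs disagreeing by more than `flag_threshold` percentage
#' points on any metric are flagged.
#'
#' @param profiles Tibble with `sample_id`, `assay_id`, `replicate` and
#'   `pct_*` columns.
#' @param flag_threshold Disagreement flag threshold in percentage
#'   points (default 10).
#' @return One row per (sample, assay) with averaged metrics and a
#'   `replicate_flag` column.
#' @export
average_replicates <- function(profiles, flag_threshold = 10) {
  wide <- profiles |>
    group_by(.data$sample_id, .data$assay_id) |>
    summarise(across(all_of(PCT_COLS),
                     list(mean = mean, spread = ~ diff(range(.x)))),
              .groups = "drop")
  spread_cols <- paste0(PCT_COLS, "_spread")
  out <- wide |>
    mutate(replicate_flag = rowSums(
      as.matrix(pick(all_of(spread_cols))) > flag_threshold) > 0) |>
    select(-all_of(spread_cols))
  names(out) <- sub("_mean$", "", names(out))
  out
}

#' Locus-specific per-CpG methylation
#'
#' After bisulfite conversion and PCR, the restriction enzyme cuts only
#' molecules that retained the methylated-site sequence, so the digested
#' fraction estimates the methylation of that CpG:
#' `100 * digested / (digested + undigested)`.
#'
#' @param x A data frame with columns `digested`, `undigested` and
#'   typically `sample_id`, `locus_id`, `cpg_index`.
#' @return The input with `pct_methylated` appended.
#' @export
locus_methylation <- function(x) {
  x <- as_tibble(x)
  check_that(all(x$digested >= 0) && all(x$undigested >= 0),
             "intensities must be >= 0")
  tot <- x$digested + x$undigested
  if (any(tot <= 0)) abort("digested + undigested must be positive")
  mutate(x, pct_methylated = 100 * .data$digested / tot)
}

#' Two-group comparison with effect size
#'
#' Pooled-variance two-sample t test (two-sided) with Cohen's d
#' (mean difference over pooled SD) and the raw case - control delta.
#'
#' @param values_case,values_ctrl Numeric vectors, each of length >= 2.
#' @return A one-row tibble: `mean_case`, `mean_ctrl`, `delta`, `t_stat`,
#'   `df`, `p_two_sided`, `cohens_d` (NA when the pooled SD is zero).
#' @export
group_compare <- function(values_case, values_ctrl) {
  check_that(length(values_case) >= 2 && length(values_ctrl) >= 2,
             "each group needs at least 2 values")
  n1 <- length(values_case); n2 <- length(values_ctrl)
  m1 <- mean(values_case); m2 <- mean(values_ctrl)
  sp2 <- ((n1 - 1) * stats::var(values_case) +
            (n2 - 1) * stats::var(values_ctrl)) / (n1 + n2 - 2)
  if (sp2 > 0) {
    tt <- t.test(values_case, values_ctrl, var.equal = TRUE)
    tibble(mean_case = m1, mean_ctrl = m2, delta = m1 - m2,
           t_stat = unname(tt$statistic), df = unname(tt$parameter),
           p_two_sided = tt$p.value, cohens_d = (m1 - m2) / sqrt(sp2))
  } else {
    tibble(mean_case = m1, mean_ctrl = m2, delta = m1 - m2,
           t_stat = if (m1 == m2) 0 else NA_real_,
           df = n1 + n2 - 2,
           p_two_sided = if (m1 == m2) 1 else NA_real_,
           cohens_d = NA_real_)
  }
}

#' Relative quantification by the 2^-ddCt method
#'
#' `ddCt = (Ct_target,sample - Ct_ref,sample) -
#' (Ct_target,calibrator - Ct_ref,calibrator)`; the fold change is
#' `2^-ddCt` exactly, so a one-cycle decrease in the sample's target Ct
#' doubles the fold.
#'
#' @param ct_target_s,ct_ref_s Sample Ct values for target and reference
#'   assays (vectors recycle one against the other).
#' @param ct_target_cal,ct_ref_cal Calibrator Ct values.
#' @return A tibble `ddct`, `fold`, `log2fold` (= `-ddct`).
#' @export
ddct_fold <- function(ct_target_s, ct_ref_s, ct_target_cal, ct_ref_cal) {
  check_that(all(is.finite(c(ct_target_s, ct_ref_s, ct_target_cal,
                             ct_ref_cal))),
             "Ct values must be finite")
  ddct <- (ct_target_s - ct_ref_s) - (ct_target_cal - ct_ref_cal)
  tibble(ddct = ddct, fold = 2^(-ddct), log2fold = -ddct)
}
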