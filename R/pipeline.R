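#' Build a pipeline run configuration
#'
#' A flat, validated key-value configuration for [run_pipeline()]:
#' input/output directories, the statistical thresholds of the analysis,
#' and the seed. Thresholds default to the conventions used throughout
#' the package: DE features at adjusted p < 0.01 and |log2FC| > 1,
#' correlation significance at FDR 0.05, PWM scanning at relative score
#' 0.8, group comparisons at alpha 0.05.
#'
#' @param input_dir Directory holding the input files (layout as written
#'   by [gen_all()]).
#' @param out_dir Output directory for stage results and the manifest.
#' @param de_padj,de_lfc DE filter thresholds.
#' @param corr_fdr Correlation FDR threshold.
#' @param scan_threshold PWM relative-score threshold.
#' @param cobra_alpha Group-comparison significance level.
#' @param seed Seed recorded in the manifest and used for any sampling
#'   inside the run (e.g. size-matching the non-DE sequence set).
#' @param simulate If `TRUE`, generate the synthetic inputs into
#'   `input_dir` first.
#' @param jaspar_pfm Optional path to a JASPAR text file of matrices to
#'   scan the DE consensus with.
#' @return A `run_config` list.
#' @export
run_config <- function(input_dir, out_dir,
                       de_padj = 0.01, de_lfc = 1, corr_fdr = 0.05,
                       scan_threshold = 0.8, cobra_alpha = 0.05,
                       seed = 1L, simulate = FALSE, jaspar_pfm = NULL) {
  check_that(de_padj > 0 && de_padj <= 1 && corr_fdr > 0 && corr_fdr <= 1 &&
               cobra_alpha > 0 && cobra_alpha <= 1 &&
               scan_threshold >= 0 && scan_threshold <= 1,
             "thresholds out of range")
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 de_padj = de_padj, de_lfc = de_lfc, corr_fdr = corr_fdr,
                 scan_threshold = scan_threshold, cobra_alpha = cobra_alpha,
                 seed = as.integer(seed), simulate = simulate,
                 jaspar_pfm = jaspar_pfm),
            class = "run_config")
}

stage_run <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)))
  })
}

need_input <- function(config, file, stage) {
  path <- file.path(config$input_dir, file)
  if (!file.exists(path)) {
    abort(sprintf("stage '%s': missing input %s (rerun the stage that produces it, or simulate)",
                  stage, path))
  }
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order - optional simulate, feature mapping,
#' cis/trans correlation, consensus/motif analysis, COBRA methylation
#' and ddCt quantification, and phenotype association - with each stage
#' reading and writing plain files, so any stage can be re-run or
#' replaced independently. A JSON manifest records thresholds, seed,
#' package version and input checksums.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage progress messages.
#' @return Invisibly, a named list of the main per-stage results.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  check_that(inherits(config, "run_config"), "config must be a run_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[alureg] ", sprintf(...))
  outp <- function(...) file.path(config$out_dir, ...)
  results <- list()

  if (isTRUE(config$simulate)) {
    say("stage simulate: writing synthetic inputs to %s", config$input_dir)
    stage_run("simulate",
              gen_all(synth_config(seed = config$seed), config$input_dir))
  }

  say("stage map-features")
  assignments <- stage_run("map-features", {
    tes <- read_bed(need_input(config, "te.bed", "map-features"))
    genes <- read_gene_table(need_input(config, "genes.tsv", "map-features"))
    a <- assign_features(tes, genes)
    readr::write_tsv(a, outp("assignments.tsv"), progress = FALSE)
    readr::write_tsv(summarize_assignments(a), outp("class_summary.tsv"),
                     progress = FALSE)
    a
  })
  results$assignments <- assignments

  say("stage correlate")
  corr <- stage_run("correlate", {
    samples <- read_sample_table(need_input(config, "samples.tsv",
                                            "correlate"))
    te_counts <- read_count_matrix(need_input(config, "te_counts.tsv",
                                              "correlate"), samples)
    gene_counts <- read_count_matrix(need_input(config, "gene_counts.tsv",
                                                "correlate"), samples)
    te_expr <- normalize_log(te_counts)
    gene_expr <- normalize_log(gene_counts)
    pairs <- assignments |>
      filter(.data$te_id %in% rownames(te_expr),
             .data$gene_id %in% rownames(gene_expr))
    cis <- cis_correlate(te_expr, gene_expr, pairs, samples,
                         fdr = config$corr_fdr)
    readr::write_tsv(tidy(cis), outp("cis_records.tsv"), progress = FALSE)
    trans <- trans_correlate(te_expr, gene_expr, samples,
                             fdr = config$corr_fdr)
    sig <- tidy(trans) |>
      filter(.data$sig_all | .data$sig_ctrl | .data$sig_case)
    readr::write_tsv(sig, outp("trans_significant.tsv"), progress = FALSE)
    readr::write_tsv(glance(trans$overlap), outp("trans_overlap.tsv"),
                     progress = FALSE)
    list(cis = cis, trans = trans)
  })
  results$cis <- corr$cis
  results$trans <- corr$trans

  say("stage motif")
  results$motif <- stage_run("motif", {
    de <- read_fasta(need_input(config, "de.fasta", "motif"))
    nonde_pool <- read_fasta(need_input(config, "nonde.fasta", "motif"))
    reference <- unname(read_fasta(need_input(config, "reference.fasta",
                                              "motif"))[1])
    nonde <- sample_matched(nonde_pool, min(length(de), length(nonde_pool)),
                            seed = config$seed)
    prof_de <- consensus_profile(align_to_reference(de, reference))
    prof_nonde <- consensus_profile(align_to_reference(nonde, reference))
    regions <- conserved_regions(prof_de, prof_nonde)
    readr::write_tsv(prof_de, outp("consensus_de.tsv"), progress = FALSE)
    readr::write_tsv(prof_nonde, outp("consensus_nonde.tsv"),
                     progress = FALSE)
    readr::write_tsv(regions, outp("conserved_regions.tsv"),
                     progress = FALSE)
    out <- list(profile_de = prof_de, profile_nonde = prof_nonde,
                regions = regions)
    if (!is.null(config$jaspar_pfm)) {
      pwms <- map(read_jaspar_pfm(config$jaspar_pfm), pfm_to_pwm)
      cons_de <- consensus_string(prof_de)
      cons_nonde <- consensus_string(prof_nonde)
      hits_de <- scan_pwm(pwms, cons_de, threshold = config$scan_threshold)
      hits_nonde <- scan_pwm(pwms, cons_nonde,
                             threshold = config$scan_threshold)
      readr::write_tsv(hits_de, outp("tfbs_hits_de.tsv"), progress = FALSE)
      readr::write_tsv(glance(compare_tf_sets(hits_de, hits_nonde)),
                       outp("tf_comparison.tsv"), progress = FALSE)
      out$hits_de <- hits_de
      out$hits_nonde <- hits_nonde
    }
    out
  })

  say("stage cobra")
  cobra_res <- stage_run("cobra", {
    bands <- readr::read_csv(need_input(config, "bands.csv", "cobra"),
                             show_col_types = FALSE, progress = FALSE)
    samples <- read_sample_table(need_input(config, "cobra_samples.tsv",
                                            "cobra"))
    prof <- average_replicates(cobra_percentages(bands))
    prof <- left_join(prof, samples, by = "sample_id")
    stats <- map_dfr(PCT_COLS, function(col) {
      gc <- group_compare(prof[[col]][prof$group == "case"],
                          prof[[col]][prof$group == "control"])
      mutate(gc, metric = col, comparison = "case_vs_ctrl",
             .before = 1)
    })
    sub_stats <- map_dfr(setdiff(unique(prof$subgroup), NA), function(sg) {
      sub <- prof |> filter(.data$subgroup %in% sg)
      ctrl <- prof |> filter(.data$group == "control",
                             .data$pair_id %in% sub$pair_id)
      if (nrow(sub) < 2 || nrow(ctrl) < 2) return(NULL)
      map_dfr(PCT_COLS, function(col) {
        mutate(group_compare(sub[[col]], ctrl[[col]]), metric = col,
               comparison = paste0(sg, "_vs_matched_ctrl"), .before = 1)
      })
    })
    stats <- bind_rows(stats, sub_stats)
    readr::write_tsv(prof, outp("cobra_profiles.tsv"), progress = FALSE)
    readr::write_tsv(stats, outp("cobra_stats.tsv"), progress = FALSE)
    list(profiles = prof, stats = stats)
  })
  results$cobra <- cobra_res

  say("stage ddct")
  folds_res <- stage_run("ddct", {
    ct <- readr::read_csv(need_input(config, "ct.csv", "ddct"),
                          show_col_types = FALSE, progress = FALSE)
    cal <- ct |> filter(.data$role == "calibrator")
    check_that(nrow(cal) >= 1, "no calibrator row in Ct table")
    smp <- ct |> filter(.data$role == "sample")
    folds <- bind_cols(
      smp[c("sample_id", "target", "reference")],
      ddct_fold(smp$ct_target, smp$ct_ref,
                cal$ct_target[1], cal$ct_ref[1]))
    readr::write_tsv(folds, outp("folds.tsv"), progress = FALSE)
    folds
  })
  results$folds <- folds_res

  say("stage assoc")
  results$assoc <- stage_run("assoc", {
    pheno <- readr::read_tsv(need_input(config, "phenotypes.tsv", "assoc"),
                             show_col_types = FALSE, progress = FALSE)
    measures <- cobra_res$profiles |>
      select("sample_id", all_of(PCT_COLS)) |>
      left_join(select(folds_res, "sample_id", alu_fold = "fold"),
                by = "sample_id")
    assoc <- assoc_matrix(measures, pheno)
    readr::write_tsv(assoc, outp("assoc.tsv"), progress = FALSE)
    assoc
  })

  inputs <- list.files(config$input_dir, full.names = TRUE)
  names(inputs) <- basename(inputs)
  manifest <- list(
    package = "alureg",
    version = as.character(utils::packageVersion("alureg")),
    seed = config$seed,
    thresholds = list(de_padj = config$de_padj, de_lfc = config$de_lfc,
                      corr_fdr = config$corr_fdr,
                      scan_threshold = config$scan_threshold,
                      cobra_alpha = config$cobra_alpha),
    inputs = as.list(setNames(unname(tools::md5sum(inputs)),
                              names(inputs)))
  )
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  say("done; outputs in %s", config$out_dir)
  invisible(results)
}
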