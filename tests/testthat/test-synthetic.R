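test_that("the full bundle is byte-identical for identical configs", {
  cfg <- synth_config(seed = 77, n_te = 40, n_gene = 40, n_seq = 30,
                      ref_length = 60, conserved_window = c(11L, 50L),
                      motif_at = 21L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  gen_all(cfg, d1)
  gen_all(cfg, d2)
  f1 <- list.files(d1)
  expect_true(length(f1) >= 10)
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
  }
})

test_that("planted genome classes are recovered through file round-trips", {
  cfg <- synth_config(seed = 13)
  d <- withr::local_tempdir()
  gen_all(synth_config(seed = 13, n_te = 50, n_gene = 50, n_seq = 10,
                       ref_length = 60, conserved_window = c(11L, 50L),
                       motif_at = 21L), d)
  tes <- read_bed(file.path(d, "te.bed"))
  genes <- read_gene_table(file.path(d, "genes.tsv"))
  truth <- readr::read_tsv(file.path(d, "truth_classes.tsv"),
                           show_col_types = FALSE)
  a <- assign_features(tes, genes, level = "transcript")
  joined <- dplyr::inner_join(truth, a, by = c("te_id", "gene_id"))
  expect_equal(nrow(joined), nrow(truth))
  expect_equal(joined$class.x, joined$class.y)
})

test_that("all-exon class mix plants every TE in an exon", {
  cfg <- synth_config(seed = 14, class_mix = c(exon = 1, intron = 0,
                                               up1k = 0, up10k = 0,
                                               up50k = 0))
  g <- gen_genome(cfg, n_te = 30, n_genes = 10)
  expect_true(all(g$truth$class == "exon"))
  a <- assign_features(g$tes, g$genes, level = "transcript")
  expect_true(all(a$class == "exon"))
})

test_that("count coupling calibration hits the target correlation", {
  rs <- sapply(1:40, function(i) {
    cfg <- synth_config(seed = 3000 + i, n_te = 40, n_gene = 40,
                        frac_linked = 0.5)
    cc <- gen_counts(cfg)
    te <- normalize_log(cc$te_counts)
    ge <- normalize_log(cc$gene_counts)
    idx <- which(cc$truth$linked)
    mean(sapply(idx, function(j) cor(te[j, ], ge[j, ])))
  })
  expect_gte(mean(rs), 0.7)
  expect_lte(mean(rs), 0.9)
})

test_that("zero coupling leaves linked pairs at the null distribution", {
  cfg <- synth_config(seed = 15, n_te = 200, n_gene = 200,
                      frac_linked = 0.5, coupling_r = 0)
  cc <- gen_counts(cfg)
  te <- normalize_log(cc$te_counts)
  ge <- normalize_log(cc$gene_counts)
  r_linked <- sapply(which(cc$truth$linked),
                     function(j) cor(te[j, ], ge[j, ]))
  r_null <- sapply(which(!cc$truth$linked),
                   function(j) cor(te[j, ], ge[j, ]))
  expect_lt(abs(mean(r_linked)) , 0.1)
  expect_lt(abs(mean(abs(r_linked)) - mean(abs(r_null))), 0.05)
})

test_that("case-only coupling separates the group correlations", {
  cfg <- synth_config(seed = 16, n_te = 100, n_gene = 100,
                      frac_linked = 0.5, coupling_mode = "case_only")
  cc <- gen_counts(cfg)
  te <- normalize_log(cc$te_counts)
  ge <- normalize_log(cc$gene_counts)
  is_case <- cc$samples$group == "case"
  gap <- sapply(which(cc$truth$linked), function(j) {
    cor(te[j, is_case], ge[j, is_case]) -
      cor(te[j, !is_case], ge[j, !is_case])
  })
  expect_gt(mean(gap), 0.4)
})

test_that("equal mutation rates leave no conserved signal beyond the motif", {
  cfg <- synth_config(seed = 17, mut_in = 0.1, mut_out = 0.1, n_seq = 200)
  sq <- gen_sequences(cfg)
  pd <- consensus_profile(align_to_reference(sq$de_seqs, sq$reference))
  pn <- consensus_profile(align_to_reference(sq$nonde_seqs, sq$reference))
  reg <- conserved_regions(pd, pn)
  # only the functional site itself (kept at mut_in / 4) may stand out;
  # every detected column must sit within a couple of bases of it
  if (nrow(reg) > 0) {
    expect_true(all(reg$start >= sq$truth$motif_start - 3 &
                      reg$end <= sq$truth$motif_end + 3))
  }
  expect_lte(nrow(reg), 1)
})

test_that("the planted motif scores high on the DE consensus only", {
  cfg <- synth_config(seed = 18)
  sq <- gen_sequences(cfg)
  pwm <- pfm_to_pwm(kmer_pfm(cfg$motif_kmer))
  cons_de <- consensus_string(consensus_profile(
    align_to_reference(sq$de_seqs, sq$reference)))
  cons_nonde <- consensus_string(consensus_profile(
    align_to_reference(sq$nonde_seqs, sq$reference)))
  expect_gte(nrow(scan_pwm(pwm, cons_de, threshold = 0.8)), 1)
  expect_equal(nrow(scan_pwm(pwm, cons_nonde, threshold = 0.8)), 0L)
})

test_that("noiseless COBRA bands invert exactly to the planted truth", {
  cfg <- synth_config(seed = 19, gel_cv = 0)
  cb <- gen_cobra(cfg)
  prof <- cobra_percentages(cb$bands)
  expect_equal(prof$pct_mC, cb$truth$true_pct_mC, tolerance = 1e-12)
  expect_equal(prof$pct_uCuC, cb$truth$true_uCuC, tolerance = 1e-12)
  expect_equal(prof$pct_uCmC, cb$truth$true_uCmC, tolerance = 1e-12)
  expect_equal(prof$pct_mCuC, cb$truth$true_mCuC, tolerance = 1e-12)
  expect_equal(prof$pct_mCmC, cb$truth$true_mCmC, tolerance = 1e-12)
})

test_that("balanced patterns give 50 percent methylation, all-mCmC gives 100", {
  cfg <- synth_config(seed = 20, gel_cv = 0,
                      meth_patterns_case = c(uCuC = 0.25, uCmC = 0.25,
                                             mCuC = 0.25, mCmC = 0.25),
                      molecules_per_assay = 4000L)
  cb <- gen_cobra(cfg)
  prof <- cobra_percentages(cb$bands)
  case_rows <- grepl("case", prof$sample_id)
  # %mC equals the realized methylated-CpG fraction; near 50 by design
  expect_equal(prof$pct_mC, cb$truth$true_pct_mC, tolerance = 1e-12)
  expect_lt(max(abs(prof$pct_mC[case_rows] - 50)), 3)

  cfg2 <- synth_config(seed = 21, gel_cv = 0,
                       meth_patterns_case = c(uCuC = 1e-9, uCmC = 1e-9,
                                              mCuC = 1e-9, mCmC = 1))
  cb2 <- gen_cobra(cfg2)
  prof2 <- cobra_percentages(cb2$bands)
  expect_equal(prof2$pct_mC[grepl("case", prof2$sample_id)],
               rep(100, sum(grepl("case", prof2$sample_id))),
               tolerance = 1e-3)
})

test_that("planted qPCR folds are recovered exactly without noise", {
  cfg <- synth_config(seed = 22)
  cb <- gen_cobra(cfg)
  meth <- cb$truth |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(true_pct_mC = mean(true_pct_mC))
  ph <- gen_phenotypes(cfg, meth, cb$samples)
  cal <- ph$ct[ph$ct$role == "calibrator", ]
  smp <- ph$ct[ph$ct$role == "sample", ]
  folds <- ddct_fold(smp$ct_target, smp$ct_ref, cal$ct_target, cal$ct_ref)
  expect_equal(folds$fold,
               ph$truth$folds$fold[match(smp$sample_id,
                                         ph$truth$folds$sample_id)])
  expect_true(all(folds$fold[smp$sample_id %in%
    cb$samples$sample_id[cb$samples$group == "case"]] == cfg$planted_fold))
})
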