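#' Configuration for the synthetic-data generators
#'
#' Collects every planted-truth parameter and the single global seed.
#' Per-generator sub-streams are derived from the seed by fixed offsets,
#' so each generator can be re-run independently yet the whole bundle is
#' byte-reproducible. Defaults emulate the study conditions the package
#' is designed for: 21 + 21 RNA-seq samples, 50 truly coupled TE-gene
#' pairs among 1000 with target correlation 0.8, a conserved promoter
#' window mutated at 0.02 against a 0.10 background over 500 repeat
#' sequences, a 7 + 6 COBRA pilot with group methylation patterns close
#' to published brain values, and phenotype scores coupled to
#' methylation at a theoretical correlation of 0.7.
#'
#' @param seed Global integer seed.
#' @param n_case,n_ctrl Sample counts for the count matrices.
#' @param n_te,n_gene Feature counts (TE loci and genes).
#' @param frac_linked Fraction of TE-gene pairs truly coupled.
#' @param coupling_r Target Pearson correlation of linked pairs on the
#'   log scale.
#' @param coupling_mode `"both_groups"` or `"case_only"`.
#' @param nb_dispersion Negative-binomial dispersion of counts.
#' @param mean_log_expr Mean log2 expression of features.
#' @param class_mix Named proportions over the five feature classes
#'   (exon, intron, up1k, up10k, up50k) for genome planting.
#' @param motif_kmer Planted promoter motif.
#' @param conserved_window Two-element column range of the conserved
#'   window on the reference.
#' @param motif_at Start column of the planted motif (inside the
#'   window).
#' @param mut_in,mut_out Per-base mutation rates inside/outside the
#'   conserved window (DE set); the non-DE set uses `mut_out`
#'   everywhere.
#' @param n_seq Sequences per set.
#' @param ref_length Reference (left-arm) length in bp.
#' @param indel_rate Per-base indel rate.
#' @param n_case_cobra,n_ctrl_cobra COBRA pilot sample counts.
#' @param meth_patterns_case,meth_patterns_ctrl Pattern probabilities
#'   (uCuC, uCmC, mCuC, mCmC), each summing to 1.
#' @param gel_cv Lognormal multiplicative noise CV on band intensities.
#' @param molecules_per_assay Molecules sampled per COBRA assay.
#' @param pheno_beta Slope coupling clinical scores to %mC.
#' @param pheno_sigma Score noise SD; `NA` derives it from `pheno_r`.
#' @param pheno_r Theoretical score-%mC correlation used when
#'   `pheno_sigma` is `NA`.
#' @param planted_fold qPCR fold change planted for case samples.
#' @param density_mean,density_sd,density_delta_sd Neuron density
#'   control mean/SD and the planted case shift in SD units.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_case = 21L, n_ctrl = 21L,
                         n_te = 1000L, n_gene = 1000L,
                         frac_linked = 0.05,
                         coupling_r = 0.8,
                         coupling_mode = c("both_groups", "case_only"),
                         nb_dispersion = 0.05,
                         mean_log_expr = 8,
                         class_mix = c(exon = 485, intron = 7232,
                                       up1k = 236, up10k = 1893,
                                       up50k = 8199) / 18045,
                         motif_kmer = "TGAGGTCAG",
                         conserved_window = c(31L, 70L),
                         motif_at = 45L,
                         mut_in = 0.02, mut_out = 0.10,
                         n_seq = 500L, ref_length = 130L,
                         indel_rate = 0.005,
                         n_case_cobra = 7L, n_ctrl_cobra = 6L,
                         meth_patterns_case = c(uCuC = 0.326, uCmC = 0.211,
                                                mCuC = 0.198, mCmC = 0.265),
                         meth_patterns_ctrl = c(uCuC = 0.323, uCmC = 0.208,
                                                mCuC = 0.193, mCmC = 0.276),
                         gel_cv = 0.05,
                         molecules_per_assay = 10000L,
                         pheno_beta = 2, pheno_sigma = NA_real_,
                         pheno_r = 0.7,
                         planted_fold = 4,
                         density_mean = 130, density_sd = 10,
                         density_delta_sd = 1) {
  coupling_mode <- match.arg(coupling_mode)
  check_that(abs(sum(class_mix) - 1) < 1e-6, "class_mix must sum to 1")
  check_that(setequal(names(class_mix), FEATURE_CLASSES),
             "class_mix needs names exon, intron, up1k, up10k, up50k")
  meth_patterns_case <- meth_patterns_case / sum(meth_patterns_case)
  meth_patterns_ctrl <- meth_patterns_ctrl / sum(meth_patterns_ctrl)
  check_that(all(c(mut_in, mut_out, indel_rate, frac_linked) >= 0 &
                   c(mut_in, mut_out, indel_rate, frac_linked) <= 1),
             "rates must lie in [0, 1]")
  check_that(conserved_window[1] >= 1 &&
               conserved_window[2] <= ref_length &&
               motif_at >= conserved_window[1] &&
               motif_at + nchar(motif_kmer) - 1 <= conserved_window[2],
             "motif must fit inside the conserved window on the reference")
  structure(as.list(environment()), class = "synth_config")
}

# fixed per-generator sub-stream offsets from the one global seed
sub_seed <- function(config, stream) {
  offs <- c(genome = 101L, counts = 202L, sequences = 303L,
            cobra = 404L, phenotypes = 505L)
  as.integer(config$seed) + offs[[stream]]
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# apportion n into integer class counts matching proportions exactly
# (largest-remainder rounding)
apportion <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic genome with planted TE feature classes
#'
#' Lays out `n_genes` gene models (1-5 exons, both strands) on one
#' chromosome in disjoint 130-kb slots with 55 kb of upstream clearance,
#' then places `n_te` TE loci so that the feature-class composition
#' matches `config$class_mix` exactly, every locus respecting a >= 10 bp
#' margin from class boundaries. The truth table records the intended
#' class per (TE, gene).
#'
#' @param config A [synth_config()].
#' @param n_te,n_genes Override counts (defaults: 200 TEs across 40
#'   genes, enough to exercise every class without an oversized genome).
#' @return A list: `genes` (gene table), `tes` (BED-shaped tibble),
#'   `truth` (tibble `te_id`, `gene_id`, `class`).
#' @export
gen_genome <- function(config, n_te = 200L, n_genes = 40L) {
  withr::with_seed(sub_seed(config, "genome"), {
    slot <- 130000L
    chrom <- "chrS1"
    genes <- map_dfr(seq_len(n_genes), function(g) {
      n_ex <- sample(1:5, 1)
      ex_len <- c(sample(400:800, 1),
                  if (n_ex > 1) sample(300:800, n_ex - 1, replace = TRUE))
      in_len <- if (n_ex > 1) sample(600:2000, n_ex - 1, replace = TRUE) else integer()
      starts <- integer(n_ex); ends <- integer(n_ex)
      pos <- (g - 1L) * slot + 55000L
      for (e in seq_len(n_ex)) {
        starts[e] <- pos
        ends[e] <- pos + ex_len[e]
        pos <- ends[e] + if (e < n_ex) in_len[e] else 0L
      }
      tibble(gene_id = sprintf("gene%04d", g),
             tx_id = sprintf("gene%04d.t1", g),
             chrom = chrom, strand = sample(c("+", "-"), 1),
             tx_start = starts[1], tx_end = ends[n_ex],
             exon_starts = list(starts), exon_ends = list(ends))
    })
    genes <- validate_gene_table(genes)
    mix <- config$class_mix[FEATURE_CLASSES]
    n_per_class <- setNames(apportion(n_te, mix), FEATURE_CLASSES)
    classes <- rep(names(n_per_class), n_per_class)
    multi_exon <- which(lengths(genes$exon_starts) > 1)
    fams <- tibble(family = c("Alu", "Alu", "Alu", "L1", "L2", "MIR"),
                   subfamily = c("AluSx", "AluY", "AluJb", "L1M", "L2a",
                                 "MIRb"))
    tes <- map_dfr(seq_along(classes), function(i) {
      cl <- classes[i]
      te_len <- sample(150:300, 1)
      g <- if (cl == "intron") sample(multi_exon, 1) else sample(n_genes, 1)
      gs <- genes$strand[g]; tss <- genes$tss[g]
      if (cl == "exon") {
        ok <- which(genes$exon_ends[[g]] - genes$exon_starts[[g]] >= te_len + 20L)
        e <- ok[sample.int(length(ok), 1)]
        lo <- genes$exon_starts[[g]][e] + 10L
        hi <- genes$exon_ends[[g]][e] - te_len - 10L
        start <- if (hi > lo) sample(lo:hi, 1) else lo
      } else if (cl == "intron") {
        es <- genes$exon_starts[[g]]; ee <- genes$exon_ends[[g]]
        gaps <- which(es[-1] - ee[-length(ee)] >= te_len + 20L)
        j <- gaps[sample.int(length(gaps), 1)]
        lo <- ee[j] + 10L
        hi <- es[j + 1] - te_len - 10L
        start <- if (hi > lo) sample(lo:hi, 1) else lo
      } else {
        lims <- switch(cl,
                       up1k = c(10L, 1000L - te_len - 10L),
                       up10k = c(1010L, 10000L - te_len - 10L),
                       up50k = c(10010L, 50000L - te_len - 10L))
        d <- sample(lims[1]:lims[2], 1)
        # d = distance from the TE edge nearest the TSS
        start <- if (gs == "+") tss - d - te_len else tss + d
      }
      fam <- fams[sample.int(nrow(fams), 1), ]
      tibble(chrom = genes$chrom[g], start = as.integer(start),
             end = as.integer(start + te_len),
             id = sprintf("te%04d", i), score = 0,
             strand = sample(c("+", "-"), 1),
             family = fam$family, subfamily = fam$subfamily,
             gene_id = genes$gene_id[g], class = cl)
    })
    list(genes = genes,
         tes = select(tes, -"gene_id", -"class"),
         truth = select(tes, "te_id" = "id", "gene_id", "class"))
  })
}

#' Generate grouped count matrices with planted TE-gene coupling
#'
#' TE and gene features are paired one-to-one; a fraction of pairs is
#' truly coupled through a shared standard-normal latent factor added to
#' both log2 means, with the latent correlation inflated to compensate
#' for counting noise so the observed log-scale Pearson correlation of a
#' linked pair is close to `coupling_r`. Counts are drawn gamma-Poisson
#' (negative binomial) with a single dispersion. In `case_only` mode the
#' factor is shared only within case samples.
#'
#' @param config A [synth_config()].
#' @return A list: `te_counts`, `gene_counts` (matrices), `samples`
#'   (sample table with subgroups and pairing), `truth` (tibble `te_id`,
#'   `gene_id`, `linked`, `mode`).
#' @export
gen_counts <- function(config) {
  withr::with_seed(sub_seed(config, "counts"), {
    n_s <- config$n_case + config$n_ctrl
    samples <- tibble(
      sample_id = c(sprintf("case%02d", seq_len(config$n_case)),
                    sprintf("ctrl%02d", seq_len(config$n_ctrl))),
      group = rep(c("case", "control"), c(config$n_case, config$n_ctrl)))
    n_nv <- ceiling(config$n_case / 2)
    samples$subgroup <- c(rep(c("NV-case", "V-case"),
                              c(n_nv, config$n_case - n_nv)),
                          rep(NA_character_, config$n_ctrl))
    npair <- min(config$n_case, config$n_ctrl)
    samples$pair_id <- NA_character_
    samples$pair_id[samples$group == "case"][seq_len(npair)] <-
      sprintf("p%02d", seq_len(npair))
    samples$pair_id[samples$group == "control"][seq_len(npair)] <-
      sprintf("p%02d", seq_len(npair))
    samples <- sample_table(samples)
    is_case <- samples$group == "case"

    n_pairs <- min(config$n_te, config$n_gene)
    n_linked <- round(config$frac_linked * n_pairs)
    linked <- seq_len(n_pairs) %in% sample(n_pairs, n_linked)
    te_ids <- sprintf("te%04d", seq_len(config$n_te))
    gene_ids <- sprintf("gene%04d", seq_len(config$n_gene))

    # latent-correlation inflation: counting noise on the log2 scale has
    # variance ~ (1/mu + phi) / ln(2)^2, attenuating the latent r
    mu_bar <- 2^config$mean_log_expr
    v_count <- (1 / mu_bar + config$nb_dispersion) / log(2)^2
    rho_l <- min(config$coupling_r * (1 + v_count), 0.995)
    a <- sqrt(rho_l)

    draw <- function(log2mu) {
      matrix(rnbinom(length(log2mu), mu = 2^log2mu,
                     size = 1 / config$nb_dispersion),
             nrow = nrow(log2mu))
    }
    mu_te <- rnorm(config$n_te, config$mean_log_expr, 1)
    mu_gene <- rnorm(config$n_gene, config$mean_log_expr, 1)
    lm_te <- matrix(rnorm(config$n_te * n_s), config$n_te, n_s)
    lm_gene <- matrix(rnorm(config$n_gene * n_s), config$n_gene, n_s)
    z <- matrix(rnorm(n_pairs * n_s), n_pairs, n_s)
    share <- if (config$coupling_mode == "case_only") {
      matrix(rep(is_case, each = n_pairs), n_pairs, n_s)
    } else {
      matrix(TRUE, n_pairs, n_s)
    }
    b <- sqrt(1 - a^2)
    for (i in which(linked)) {
      sh <- share[i, ]
      lm_te[i, sh] <- a * z[i, sh] + b * lm_te[i, sh]
      lm_gene[i, sh] <- a * z[i, sh] + b * lm_gene[i, sh]
    }
    te_counts <- draw(mu_te + lm_te)
    gene_counts <- draw(mu_gene + lm_gene)
    dimnames(te_counts) <- list(te_ids, samples$sample_id)
    dimnames(gene_counts) <- list(gene_ids, samples$sample_id)
    truth <- tibble(te_id = te_ids[seq_len(n_pairs)],
                    gene_id = gene_ids[seq_len(n_pairs)],
                    linked = linked, mode = config$coupling_mode)
    list(te_counts = te_counts, gene_counts = gene_counts,
         samples = samples, truth = truth)
  })
}

mutate_seq <- function(bases, rates) {
  hit <- runif(length(bases)) < rates
  if (any(hit)) {
    bases[hit] <- vapply(bases[hit], function(b) {
      sample(setdiff(DNA_BASES, b), 1)
    }, character(1))
  }
  bases
}

apply_indels <- function(bases, rate) {
  if (rate <= 0) return(bases)
  u <- runif(length(bases))
  del <- u < rate / 2
  ins <- u >= rate / 2 & u < rate
  if (!any(del) && !any(ins)) return(bases)
  out <- as.list(bases)
  out[del] <- list(character(0))
  out[ins] <- map(bases[ins], function(b) c(b, sample(DNA_BASES, 1)))
  unlist(out)
}

#' Generate repeat sequence sets with a planted conserved window
#'
#' Builds a random reference "left arm" that carries the promoter motif
#' inside the conserved window (as the ancestral element would). The DE
#' set mutates the reference at `mut_in` inside the window (motif
#' positions at `mut_in / 4`, keeping the functional site intact) and
#' `mut_out` elsewhere. The non-DE set derives from a template whose
#' motif positions are deterministically substituted - a decayed
#' promoter - and is mutated at `mut_out` everywhere, so the motif is
#' recoverable from the DE consensus only. Small indels perturb lengths
#' at `indel_rate`.
#'
#' @param config A [synth_config()].
#' @return A list: `de_seqs`, `nonde_seqs` (named character vectors),
#'   `reference`, `truth` (window/motif coordinates tibble).
#' @export
gen_sequences <- function(config) {
  withr::with_seed(sub_seed(config, "sequences"), {
    ref <- strsplit(random_dna(config$ref_length), "")[[1]]
    w1 <- config$conserved_window[1]; w2 <- config$conserved_window[2]
    motif <- strsplit(config$motif_kmer, "")[[1]]
    m1 <- config$motif_at; m2 <- m1 + length(motif) - 1L
    ref[m1:m2] <- motif
    # decayed promoter: every motif base cycled to the next base, so the
    # non-DE template mismatches the site at all positions
    decay <- DNA_BASES[(match(motif, DNA_BASES)) %% 4 + 1]
    nonde_template <- ref
    nonde_template[m1:m2] <- decay
    rates_de <- rep(config$mut_out, config$ref_length)
    rates_de[w1:w2] <- config$mut_in
    rates_de[m1:m2] <- config$mut_in / 4
    rates_nonde <- rep(config$mut_out, config$ref_length)
    gen_set <- function(template, rates, prefix) {
      out <- vapply(seq_len(config$n_seq), function(i) {
        paste(apply_indels(mutate_seq(template, rates), config$indel_rate),
              collapse = "")
      }, character(1))
      setNames(out, sprintf("%s%04d", prefix, seq_len(config$n_seq)))
    }
    list(de_seqs = gen_set(ref, rates_de, "de"),
         nonde_seqs = gen_set(nonde_template, rates_nonde, "nonde"),
         reference = paste(ref, collapse = ""),
         truth = tibble(window_start = w1, window_end = w2,
                        motif_kmer = config$motif_kmer,
                        motif_start = m1, motif_end = m2))
  })
}

#' Generate COBRA band intensities from known methylation states
#'
#' Per sample and replicate, molecule pattern counts are multinomial
#' draws from the group's pattern probabilities; bands follow the
#' generative band map `A = n_uCuC`, `C = n_uCmC`, `D = n_mCuC`,
#' `F = n_mCmC`, `B = D + F`, `E = C + F`, under which the COBRA
#' formulas are the exact algebraic inverse (so [cobra_percentages()]
#' recovers the realized pattern fractions exactly in the noiseless
#' case, and %mC equals the true methylated-CpG fraction). Lognormal
#' multiplicative noise with CV `gel_cv` is applied per band.
#'
#' @param config A [synth_config()].
#' @return A list: `bands` (tibble `sample_id`, `assay_id`, `replicate`,
#'   `A`-`F`), `truth` (realized pattern fractions and true %mC per
#'   sample x replicate, in percent), `samples`.
#' @export
gen_cobra <- function(config) {
  withr::with_seed(sub_seed(config, "cobra"), {
    n_nv <- ceiling(config$n_case_cobra / 2)
    samples <- tibble(
      sample_id = c(sprintf("br_case%02d", seq_len(config$n_case_cobra)),
                    sprintf("br_ctrl%02d", seq_len(config$n_ctrl_cobra))),
      group = rep(c("case", "control"),
                  c(config$n_case_cobra, config$n_ctrl_cobra)),
      subgroup = c(rep(c("NV-case", "V-case"),
                       c(n_nv, config$n_case_cobra - n_nv)),
                   rep(NA_character_, config$n_ctrl_cobra)))
    npair <- min(config$n_case_cobra, config$n_ctrl_cobra)
    samples$pair_id <- NA_character_
    samples$pair_id[seq_len(npair)] <- sprintf("bp%02d", seq_len(npair))
    samples$pair_id[config$n_case_cobra + seq_len(npair)] <-
      sprintf("bp%02d", seq_len(npair))
    samples <- sample_table(samples)
    sigma <- sqrt(log(1 + config$gel_cv^2))
    rows <- map_dfr(seq_len(nrow(samples)), function(i) {
      probs <- if (samples$group[i] == "case") {
        config$meth_patterns_case
      } else {
        config$meth_patterns_ctrl
      }
      map_dfr(1:2, function(rep_i) {
        nmol <- rmultinom(1, config$molecules_per_assay, probs)[, 1]
        A <- nmol[["uCuC"]]; C <- nmol[["uCmC"]]
        D <- nmol[["mCuC"]]; F_ <- nmol[["mCmC"]]
        bands <- c(A = A, B = D + F_, C = C, D = D, E = C + F_, F = F_)
        noisy <- bands * rlnorm(6, meanlog = -sigma^2 / 2, sdlog = sigma)
        nm <- config$molecules_per_assay
        tibble(sample_id = samples$sample_id[i], assay_id = "AluSx_global",
               replicate = rep_i,
               A = noisy[["A"]], B = noisy[["B"]], C = noisy[["C"]],
               D = noisy[["D"]], E = noisy[["E"]], F = noisy[["F"]],
               true_uCuC = 100 * A / nm, true_uCmC = 100 * C / nm,
               true_mCuC = 100 * D / nm, true_mCmC = 100 * F_ / nm,
               true_pct_mC = 100 * (C + D + 2 * F_) / (2 * nm))
      })
    })
    band_cols <- c("sample_id", "assay_id", "replicate",
                   "A", "B", "C", "D", "E", "F")
    list(bands = rows[band_cols],
         truth = rows[c("sample_id", "replicate",
                        grep("^true_", names(rows), value = TRUE))],
         samples = samples)
  })
}

#' Generate phenotype scores and qPCR Ct tables coupled to methylation
#'
#' Clinical-interview-like scores for case samples follow
#' `score = intercept + pheno_beta * pct_mC + Normal(0, pheno_sigma)`;
#' when `pheno_sigma` is `NA` it is derived from the empirical SD of the
#' methylation truth so the theoretical correlation equals `pheno_r`.
#' Neuron densities get a planted case shift of `density_delta_sd`
#' pooled SDs. Ct tables are built so that [ddct_fold()] recovers the
#' planted fold exactly.
#'
#' @param config A [synth_config()].
#' @param truth_meth Tibble `sample_id`, `true_pct_mC` (e.g. averaged
#'   from [gen_cobra()] truth) covering at least the case samples.
#' @param samples The COBRA sample table.
#' @return A list: `phenotypes` (tibble with score columns and
#'   `neuron_density`), `ct` (long Ct table), `truth` (planted slopes,
#'   noise SD and folds).
#' @export
gen_phenotypes <- function(config, truth_meth, samples) {
  withr::with_seed(sub_seed(config, "phenotypes"), {
    samples <- sample_table(samples)
    case_ids <- samples$sample_id[samples$group == "case"]
    x <- truth_meth$true_pct_mC[match(case_ids, truth_meth$sample_id)]
    check_that(!anyNA(x), "methylation truth missing for case samples")
    sigma <- config$pheno_sigma
    if (is.na(sigma)) {
      sigma <- config$pheno_beta * sd(x) *
        sqrt(1 / config$pheno_r^2 - 1)
    }
    domains <- c("adir_a", "adir_b_nv", "adir_b_v", "adir_c", "adir_d")
    scores <- map(domains, function(d) {
      intercept <- 20 - config$pheno_beta * mean(x)
      pmin(pmax(intercept + config$pheno_beta * x + rnorm(length(x), 0, sigma),
                0), 40)
    })
    names(scores) <- domains
    pheno_case <- as_tibble(c(list(sample_id = case_ids), scores))
    dens <- tibble(
      sample_id = samples$sample_id,
      neuron_density = rnorm(nrow(samples), config$density_mean,
                             config$density_sd) +
        ifelse(samples$group == "case",
               config$density_delta_sd * config$density_sd, 0))
    phenotypes <- dens |> left_join(pheno_case, by = "sample_id")
    fold <- ifelse(samples$group == "case", config$planted_fold, 1)
    ct <- tibble(sample_id = samples$sample_id, target = "AluSx",
                 reference = "18S",
                 ct_target = 25 - log2(fold), ct_ref = 15,
                 role = "sample") |>
      bind_rows(tibble(sample_id = "calibrator", target = "AluSx",
                       reference = "18S", ct_target = 25, ct_ref = 15,
                       role = "calibrator"))
    list(phenotypes = phenotypes, ct = ct,
         truth = list(pheno_beta = config$pheno_beta, pheno_sigma = sigma,
                      folds = tibble(sample_id = samples$sample_id,
                                     fold = fold)))
  })
}

#' Generate the full synthetic bundle and write it to disk
#'
#' Runs every generator and writes genome, counts, sequences, COBRA,
#' phenotype and Ct files plus machine-readable truth tables and a JSON
#' manifest echoing the configuration and seed.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of written paths.
#' @export
gen_all <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  genome <- gen_genome(config)
  write_gene_table(genome$genes, p("genes.tsv"))
  write_bed(genome$tes, p("te.bed"))
  readr::write_tsv(genome$truth, p("truth_classes.tsv"), progress = FALSE)
  counts <- gen_counts(config)
  write_count_matrix(counts$te_counts, p("te_counts.tsv"))
  write_count_matrix(counts$gene_counts, p("gene_counts.tsv"))
  readr::write_tsv(counts$samples, p("samples.tsv"), progress = FALSE)
  readr::write_tsv(counts$truth, p("truth_pairs.tsv"), progress = FALSE)
  seqs <- gen_sequences(config)
  write_fasta(seqs$de_seqs, p("de.fasta"))
  write_fasta(seqs$nonde_seqs, p("nonde.fasta"))
  write_fasta(c(reference = seqs$reference), p("reference.fasta"))
  readr::write_tsv(seqs$truth, p("truth_motif.tsv"), progress = FALSE)
  cobra <- gen_cobra(config)
  readr::write_csv(cobra$bands, p("bands.csv"), progress = FALSE)
  readr::write_tsv(cobra$truth, p("truth_meth.tsv"), progress = FALSE)
  readr::write_tsv(cobra$samples, p("cobra_samples.tsv"), progress = FALSE)
  meth_avg <- cobra$truth |>
    group_by(.data$sample_id) |>
    summarise(true_pct_mC = mean(.data$true_pct_mC), .groups = "drop")
  pheno <- gen_phenotypes(config, meth_avg, cobra$samples)
  readr::write_tsv(pheno$phenotypes, p("phenotypes.tsv"), progress = FALSE)
  readr::write_csv(pheno$ct, p("ct.csv"), progress = FALSE)
  readr::write_tsv(pheno$truth$folds, p("truth_folds.tsv"), progress = FALSE)
  manifest <- list(seed = config$seed, config = unclass(config))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  invisible(list(dir = dir, files = list.files(dir, full.names = TRUE)))
}
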