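test_that("size-matched sampling is deterministic and exhaustive at n = pool", {
  pool <- setNames(replicate(20, random_seq(10)), paste0("s", 1:20))
  a <- sample_matched(pool, 5, seed = 7)
  b <- sample_matched(pool, 5, seed = 7)
  expect_identical(a, b)
  expect_setequal(names(sample_matched(pool, 20, seed = 1)), names(pool))
  expect_error(sample_matched(pool, 21, seed = 1), "pool")
})

test_that("reference alignment handles identity, gaps and projection", {
  al <- align_to_reference(c(x = "ACGGT"), "ACGGT")
  expect_equal(unname(al$rows), "ACGGT")

  # deletion relative to the reference appears as a gap
  al2 <- align_to_reference(c(x = "ACGT"), "ACGGT")
  expect_equal(unname(al2$rows), "ACG-T")
  expect_equal(al2$scores, 4 - 2)

  # insertion relative to the reference is dropped in projection
  al3 <- align_to_reference(c(x = "ACTTA"), "ACTA")
  expect_equal(nchar(unname(al3$rows)), 4L)
  expect_equal(al3$n_insertions_dropped, 1L)

  expect_warning(align_to_reference(c(x = "", y = "ACGT"), "ACGT"),
                 "empty")
})

test_that("alignment scores equal the exhaustive-enumeration oracle", {
  withr::local_seed(21)
  for (i in 1:25) {
    a <- random_seq(sample(3:8, 1))
    b <- random_seq(sample(3:8, 1))
    got <- align_to_reference(setNames(a, "q"), b)$scores
    expect_equal(got, align_score_oracle(a, b),
                 info = paste(a, "vs", b))
  }
})

test_that("consensus profile counts, ties and degenerate columns", {
  rows <- c("AA", "AC", "TG", "AT")
  prof <- consensus_profile(rows)
  expect_equal(prof$consensus[1], "A")
  expect_equal(prof$conservation[1], 0.75)
  # column 2: one each of A, C, G, T -> alphabetical tie-break
  expect_equal(prof$consensus[2], "A")
  expect_equal(prof$conservation[2], 0.25)

  ident <- consensus_profile(rep("ACGT", 5))
  expect_true(all(ident$conservation == 1))
  expect_equal(consensus_string(ident), "ACGT")

  gappy <- consensus_profile(c("A-", "A-", "A-"))
  expect_equal(gappy$consensus[2], "N")
  expect_equal(gappy$conservation[2], 0)
  # frequencies sum to 1 where coverage > 0
  expect_equal(rowSums(as.matrix(prof[c("A", "C", "G", "T")])),
               rep(1, 2), ignore_attr = TRUE)
})

test_that("random rows converge to conservation 1/4", {
  withr::local_seed(3)
  rows <- replicate(10000, random_seq(4))
  prof <- consensus_profile(rows)
  expect_true(all(abs(prof$conservation - 0.25) < 0.02))
})

test_that("conserved regions require the delta and the minimum run", {
  base <- consensus_profile(rep("ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT",
                                3))
  hi <- base; lo <- base
  hi$conservation <- rep(0.60, 40)
  lo$conservation <- rep(0.60, 40)
  hi$conservation[10:30] <- 0.95
  r <- conserved_regions(hi, lo, delta = 0.1, min_run = 5)
  expect_equal(r[c("start", "end")], tibble::tibble(start = 10L, end = 30L))

  expect_equal(nrow(conserved_regions(base, base)), 0L)

  short <- lo
  short$conservation[5:8] <- 0.95  # run of 4 < min_run
  expect_equal(nrow(conserved_regions(short, lo, min_run = 5)), 0L)
})

test_that("PFM to PWM conversion matches the hand computation", {
  pwm <- pfm_to_pwm(toy_pfm(matrix(c(8, 0, 0, 0), 4, 1)))
  expect_equal(unname(pwm$weights["A", 1]), log2((8.2 / 8.8) / 0.25),
               tolerance = 1e-12)
  expect_equal(unname(pwm$weights["A", 1]), 1.898, tolerance = 1e-3)

  # uniform column carries no information
  unif <- pfm_to_pwm(toy_pfm(matrix(rep(100, 4), 4, 1)))
  expect_true(all(abs(unif$weights) < 0.01))

  expect_error(pfm_to_pwm(toy_pfm(matrix(c(-1, 1, 1, 1), 4, 1))),
               "non-negative")
})

test_that("smin and smax bound every k-mer score (brute force, L <= 5)", {
  withr::local_seed(10)
  for (L in c(2, 4, 5)) {
    pwm <- pfm_to_pwm(toy_pfm(matrix(rpois(4 * L, 5), 4, L)))
    kmers <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), L)), 1,
                   paste, collapse = "")
    rel <- relative_score(pwm, kmers)
    expect_true(all(rel >= -1e-12 & rel <= 1 + 1e-12))
    expect_equal(max(rel), 1, tolerance = 1e-12)
    expect_equal(min(rel), 0, tolerance = 1e-12)
  }
})

test_that("relative score matches the two-column hand example", {
  pwm <- pfm_to_pwm(toy_pfm(matrix(c(8, 0, 0, 0,
                                     4, 4, 0, 0), 4, 2)))
  expect_equal(relative_score(pwm, "CC"), 0.4505, tolerance = 1e-4)
  # best k-mer scores exactly 1
  expect_equal(relative_score(pwm, "AA"), 1, tolerance = 1e-12)
  expect_error(relative_score(pwm, "AN"), "ambiguous")
  # invariant to adding a constant to all weights of a column
  shifted <- pwm
  shifted$weights[, 1] <- shifted$weights[, 1] + 3
  shifted$smin <- shifted$smin + 3
  shifted$smax <- shifted$smax + 3
  expect_equal(relative_score(shifted, "CC"), relative_score(pwm, "CC"),
               tolerance = 1e-12)
})

test_that("scanning finds the consensus site at score 1", {
  pwm <- pfm_to_pwm(kmer_pfm("TGACGTCA"))
  hits <- scan_pwm(pwm, "TGACGTCAAA", threshold = 0.8)
  top <- hits[hits$strand == "+", ][1, ]
  expect_equal(top$start, 1L)
  expect_equal(top$relative_score, 1, tolerance = 1e-12)
  expect_equal(top$site, "TGACGTCA")
  # palindromic matrix: paired +/- hits at the same span
  expect_true(all(c("+", "-") %in% hits$strand[hits$start == 1]))
})

test_that("scanning agrees with exhaustive window scoring", {
  withr::local_seed(31)
  for (i in 1:10) {
    L <- sample(3:6, 1)
    pwm <- pfm_to_pwm(toy_pfm(matrix(rpois(4 * L, 4), 4, L)))
    seq <- random_seq(sample(20:50, 1))
    got <- as.data.frame(scan_pwm(pwm, seq, threshold = 0.6))
    want <- scan_oracle(pwm, seq, threshold = 0.6)
    ord <- function(d) d[order(d$start, d$strand), ]
    got <- ord(got[c("start", "end", "strand", "site", "relative_score")])
    want <- ord(want)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("reverse-complementing the sequence mirrors hits", {
  withr::local_seed(17)
  pwm <- pfm_to_pwm(toy_pfm(matrix(rpois(20, 4), 4, 5)))
  seq <- random_seq(40)
  fwd <- scan_pwm(pwm, seq, threshold = 0.5)
  rc <- scan_pwm(pwm, revcomp(seq), threshold = 0.5)
  # same number of hits per strand, swapped, with mirrored coordinates
  expect_equal(sum(fwd$strand == "+"), sum(rc$strand == "-"))
  expect_equal(sort(41 - fwd$end[fwd$strand == "+"]),
               sort(rc$start[rc$strand == "-"]))
  expect_setequal(fwd$site, rc$site)
})

test_that("TF set comparison algebra and planted-motif uniqueness", {
  hits <- function(tfs) tibble::tibble(tf_name = tfs)
  cmp <- compare_tf_sets(hits(c("X", "Y", "Z")), hits("Y"))
  expect_setequal(cmp$unique_de, c("X", "Z"))
  expect_equal(length(compare_tf_sets(hits("A"), hits("A"))$unique_de), 0L)

  cmp2 <- compare_tf_sets(hits(c("X", "Y")), hits("Y"),
                          panel = c("X", "Q"), background_n = 100)
  expect_equal(cmp2$unique_de_in_panel, "X")
  expect_true(cmp2$enrichment_p <= 1 && cmp2$enrichment_p > 0)

  # motif planted only in the DE set puts its TF in unique_de
  cfg <- synth_config(seed = 5)
  sq <- gen_sequences(cfg)
  pwm <- pfm_to_pwm(kmer_pfm(cfg$motif_kmer))
  cons_de <- consensus_string(consensus_profile(
    align_to_reference(sq$de_seqs[1:100], sq$reference)))
  cons_nonde <- consensus_string(consensus_profile(
    align_to_reference(sq$nonde_seqs[1:100], sq$reference)))
  cmp3 <- compare_tf_sets(scan_pwm(pwm, cons_de),
                          scan_pwm(pwm, cons_nonde))
  expect_equal(cmp3$unique_de, cfg$motif_kmer)
})
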