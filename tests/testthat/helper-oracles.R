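# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately avoid the code paths they verify.

# Benjamini-Hochberg step-up by direct definition:
# adj_(i) = min_{j >= i} p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(ranked[i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric probability by enumerating every draw of
# size n from a background of size N containing K marked elements.
hypergeom_oracle <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# Optimal global alignment score (match +1, mismatch -1, gap -2) by
# exhaustive recursion over all alignments; feasible for <= 8 nt.
align_score_oracle <- function(a, b) {
  if (nchar(a) == 0) return(-2L * nchar(b))
  if (nchar(b) == 0) return(-2L * nchar(a))
  a1 <- substr(a, 1, 1); b1 <- substr(b, 1, 1)
  ra <- substr(a, 2, nchar(a)); rb <- substr(b, 2, nchar(b))
  max(align_score_oracle(ra, rb) + if (a1 == b1) 1L else -1L,
      align_score_oracle(ra, b) - 2L,
      align_score_oracle(a, rb) - 2L)
}

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Exhaustive PWM window scoring on both strands.
scan_oracle <- function(pwm, sequence, threshold) {
  L <- ncol(pwm$weights)
  n <- nchar(sequence)
  out <- list()
  for (s in seq_len(n - L + 1)) {
    win <- substr(sequence, s, s + L - 1)
    for (str in c("+", "-")) {
      km <- if (str == "+") win else oracle_revcomp(win)
      bases <- strsplit(km, "")[[1]]
      idx <- match(bases, c("A", "C", "G", "T"))
      sc <- sum(pwm$weights[cbind(idx, seq_len(L))])
      rel <- (sc - pwm$smin) / (pwm$smax - pwm$smin)
      if (rel >= threshold) {
        out[[length(out) + 1]] <- data.frame(
          start = s, end = s + L - 1, strand = str, site = km,
          relative_score = rel)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), site = character(),
                      relative_score = double()))
  }
  do.call(rbind, out)
}

# Per-base feature classifier: classify every base of a TE against one
# transcript, then combine by class precedence. Independent of the
# interval arithmetic in assign_features().
perbase_class <- function(te_start, te_end, gene_row) {
  es <- gene_row$exon_starts[[1]]
  ee <- gene_row$exon_ends[[1]]
  tss <- if (gene_row$strand == "+") gene_row$tx_start else gene_row$tx_end
  classes <- character(0)
  for (b in te_start:(te_end - 1)) {
    if (any(b >= es & b < ee)) {
      classes <- c(classes, "exon")
    } else if (b >= gene_row$tx_start && b < gene_row$tx_end) {
      classes <- c(classes, "intron")
    } else {
      d <- if (gene_row$strand == "+") tss - b - 1 else b - tss
      if (d >= 0 && d <= 1000) classes <- c(classes, "up1k")
      else if (d > 1000 && d <= 10000) classes <- c(classes, "up10k")
      else if (d > 10000 && d <= 50000) classes <- c(classes, "up50k")
    }
  }
  if (length(classes) == 0) return(NA_character_)
  prec <- c("exon", "intron", "up1k", "up10k", "up50k")
  prec[min(match(classes, prec))]
}
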