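# Small in-code fixture builders shared across test files.

# one-transcript gene table; exons is a list of c(start, end)
gene_tbl <- function(exons, strand = "+", gene_id = "g1",
                     tx_id = paste0(gene_id, ".t1"), chrom = "chr1") {
  es <- vapply(exons, `[`, numeric(1), 1)
  ee <- vapply(exons, `[`, numeric(1), 2)
  validate_gene_table(tibble::tibble(
    gene_id = gene_id, tx_id = tx_id, chrom = chrom, strand = strand,
    tx_start = as.integer(min(es)), tx_end = as.integer(max(ee)),
    exon_starts = list(as.integer(es)), exon_ends = list(as.integer(ee))))
}

te_tbl <- function(start, end, id = paste0("te", seq_along(start)),
                   chrom = "chr1", strand = "+") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), id = id, score = 0,
                 strand = strand, family = NA_character_,
                 subfamily = NA_character_)
}

# a jaspar_pfm built from counts given column-wise
toy_pfm <- function(counts, matrix_id = "TOY", tf_name = "TOY") {
  m <- as.matrix(counts)
  rownames(m) <- c("A", "C", "G", "T")
  structure(list(matrix_id = matrix_id, tf_name = tf_name, counts = m),
            class = "jaspar_pfm")
}

# strongly informative PFM for a given k-mer (used to plant/scan motifs)
kmer_pfm <- function(kmer, strong = 20, weak = 0.1) {
  b <- strsplit(kmer, "")[[1]]
  m <- matrix(weak, 4, length(b),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(b)) m[b[j], j] <- strong
  toy_pfm(m, matrix_id = paste0("KMER_", kmer), tf_name = kmer)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
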