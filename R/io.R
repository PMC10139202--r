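#' Read a BED file of TE loci
#'
#' Reads BED3/BED6 intervals (0-based, half-open, the convention used
#' throughout this package). The name column is preserved as the locus id;
#' when it is formatted `"family|subfamily|id"` (the RepeatMasker triple
#' carried through a BED export) the three parts are split out.
#'
#' @param path Path to a BED file (3 or 6+ tab-separated columns).
#' @return A tibble with columns `chrom`, `start`, `end`, `id`, `score`,
#'   `strand`, `family`, `subfamily`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  id = character(), score = double(), strand = character(),
                  family = character(), subfamily = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3 & nf < 6)) {
    bad <- which(nf != 3 & nf < 6)[1]
    abort(sprintf("malformed BED line %d: %d column(s), need 3 or >= 6",
                  bad, nf[bad]))
  }
  get <- function(i) map_chr(fields, function(f) if (length(f) >= i) f[i] else NA_character_)
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    abort(sprintf("malformed BED line %d: non-integer coordinates", bad[1]))
  }
  bad <- which(start >= end)
  if (length(bad) > 0) {
    abort(sprintf("malformed BED line %d: start >= end (empty interval)", bad[1]))
  }
  name <- ifelse(nf >= 4, get(4), NA_character_)
  name[is.na(name)] <- paste0("bed_", which(is.na(name)))
  score <- ifelse(nf >= 5, suppressWarnings(as.numeric(get(5))), 0)
  score[is.na(score)] <- 0
  strand <- ifelse(nf >= 6, get(6), ".")
  if (!all(strand %in% c("+", "-", "."))) {
    bad <- which(!strand %in% c("+", "-", "."))[1]
    abort(sprintf("malformed BED line %d: strand must be +, - or .", bad))
  }
  parts <- strsplit(name, "|", fixed = TRUE)
  triple <- lengths(parts) == 3
  part_or <- function(k, default) {
    map_chr(seq_along(parts), function(i) {
      if (triple[i]) parts[[i]][k] else default[i]
    })
  }
  tibble(
    chrom = get(1), start = start, end = end,
    id = part_or(3, name),
    score = score, strand = strand,
    family = part_or(1, rep(NA_character_, length(name))),
    subfamily = part_or(2, rep(NA_character_, length(name)))
  )
}

#' Write TE loci back to BED6
#'
#' Coordinates are written exactly as stored (0-based half-open); when
#' `family` and `subfamily` are present the name field is the
#' `"family|subfamily|id"` triple so the annotation survives a round-trip.
#'
#' @param x A tibble as returned by [read_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  name <- ifelse(!is.na(x$family) & !is.na(x$subfamily),
                 paste(x$family, x$subfamily, x$id, sep = "|"), x$id)
  writeLines(sprintf("%s\t%d\t%d\t%s\t%g\t%s",
                     x$chrom, x$start, x$end, name, x$score, x$strand),
             path)
  invisible(path)
}

#' Read a refFlat-like gene model table
#'
#' One row per transcript with columns `geneName`, `txName` (alias `name`),
#' `chrom`, `strand`, `txStart`, `txEnd`, `exonStarts`, `exonEnds`
#' (comma-separated block lists, 0-based half-open). The transcription
#' start site is `txStart` on the plus strand and `txEnd` on the minus
#' strand.
#'
#' @param path Path to a tab-separated refFlat-like file with a header.
#' @return A tibble with one row per transcript: `gene_id`, `tx_id`,
#'   `chrom`, `strand`, `tx_start`, `tx_end`, `tss`, and list-columns
#'   `exon_starts`, `exon_ends`.
#' @export
read_gene_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(exonStarts = "c",
                                                 exonEnds = "c",
                                                 .default = readr::col_guess()))
  need <- c("geneName", "chrom", "strand", "txStart", "txEnd",
            "exonStarts", "exonEnds")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(paste0("gene table missing column(s): ", paste(miss, collapse = ", ")))
  }
  tx <- raw[["txName"]] %||% raw[["name"]] %||% paste0(raw$geneName, ".tx")
  split_blocks <- function(s) {
    map(strsplit(s, ",", fixed = TRUE), function(v) as.integer(v[nzchar(v)]))
  }
  out <- tibble(
    gene_id = raw$geneName, tx_id = tx, chrom = raw$chrom,
    strand = raw$strand,
    tx_start = as.integer(raw$txStart), tx_end = as.integer(raw$txEnd),
    exon_starts = split_blocks(raw$exonStarts),
    exon_ends = split_blocks(raw$exonEnds)
  )
  validate_gene_table(out)
}

#' Validate an in-memory gene model table
#'
#' @param x A tibble shaped like the return value of [read_gene_table()]
#'   (`tss` may be absent; it is derived from the strand).
#' @return The validated tibble, with `tss` filled in.
#' @export
validate_gene_table <- function(x) {
  x <- as_tibble(x)
  check_that(all(x$strand %in% c("+", "-")), "gene strand must be + or -")
  n_s <- lengths(x$exon_starts)
  n_e <- lengths(x$exon_ends)
  if (any(n_s != n_e)) {
    bad <- which(n_s != n_e)[1]
    abort(sprintf("transcript %s: exonStarts/exonEnds length mismatch (%d vs %d)",
                  x$tx_id[bad], n_s[bad], n_e[bad]))
  }
  for (i in seq_len(nrow(x))) {
    es <- x$exon_starts[[i]]; ee <- x$exon_ends[[i]]
    check_that(all(es < ee), sprintf("transcript %s: empty exon", x$tx_id[i]))
    if (length(es) > 1) {
      check_that(all(diff(es) > 0) && all(ee[-length(ee)] <= es[-1]),
                 sprintf("transcript %s: exons overlap or are unsorted", x$tx_id[i]))
    }
    check_that(es[1] >= x$tx_start[i] && ee[length(ee)] <= x$tx_end[i],
               sprintf("transcript %s: exons outside transcript span", x$tx_id[i]))
  }
  x$tss <- ifelse(x$strand == "+", x$tx_start, x$tx_end)
  x
}

#' Write a gene model table in refFlat-like layout
#'
#' @param x A gene table as returned by [read_gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(x, path) {
  join_blocks <- function(v) paste0(paste(v, collapse = ","), ",")
  out <- tibble(
    geneName = x$gene_id, txName = x$tx_id, chrom = x$chrom,
    strand = x$strand, txStart = x$tx_start, txEnd = x$tx_end,
    exonCount = lengths(x$exon_starts),
    exonStarts = map_chr(x$exon_starts, join_blocks),
    exonEnds = map_chr(x$exon_ends, join_blocks)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR text format: a `">ID NAME"` header followed by four
#' base rows (`A`, `C`, `G`, `T`), each either bracketed
#' (`A [ 8 4 ]`) or bare space-separated counts. Both dialects parse
#' identically. Column sums are allowed to differ by at most one count
#' across columns (rounding in curated matrices); larger imbalance
#' triggers a warning.
#'
#' @param path Path to a JASPAR text file with one or more matrices.
#' @return A list of `jaspar_pfm` objects; each has `matrix_id`,
#'   `tf_name`, and a 4 x L `counts` matrix with rows A, C, G, T.
#' @export
read_jaspar_pfm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  check_that(length(heads) > 0, "no '>' header found in JASPAR file")
  bounds <- c(heads, length(lines) + 1L)
  out <- vector("list", length(heads))
  for (k in seq_along(heads)) {
    block <- lines[heads[k]:(bounds[k + 1] - 1L)]
    hdr <- sub("^>\\s*", "", block[1])
    hdr_parts <- strsplit(hdr, "\\s+")[[1]]
    matrix_id <- hdr_parts[1]
    tf_name <- if (length(hdr_parts) > 1) paste(hdr_parts[-1], collapse = " ") else matrix_id
    body <- block[-1]
    if (length(body) != 4) {
      abort(sprintf("matrix %s: expected 4 base rows, found %d",
                    matrix_id, length(body)))
    }
    rows <- map(body, function(l) {
      base <- toupper(sub("^\\s*([ACGTacgt]).*$", "\\1", l))
      nums <- gsub("[][ACGTacgt]", " ", l)
      vals <- as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
      list(base = base, vals = vals)
    })
    bases <- map_chr(rows, "base")
    if (!setequal(bases, DNA_BASES)) {
      abort(sprintf("matrix %s: base rows must be A, C, G, T (got %s)",
                    matrix_id, paste(bases, collapse = ", ")))
    }
    lens <- map_int(rows, function(r) length(r$vals))
    check_that(length(unique(lens)) == 1,
               sprintf("matrix %s: rows have unequal lengths", matrix_id))
    counts <- do.call(rbind, map(rows, "vals"))
    rownames(counts) <- bases
    counts <- counts[DNA_BASES, , drop = FALSE]
    if (any(is.na(counts))) {
      abort(sprintf("matrix %s: non-numeric count", matrix_id))
    }
    if (any(counts < 0)) {
      abort(sprintf("matrix %s: negative count", matrix_id))
    }
    cs <- colSums(counts)
    if (diff(range(cs)) > 1) {
      warn(sprintf("matrix %s: column sums differ by more than 1 (range %g-%g)",
                   matrix_id, min(cs), max(cs)))
    }
    out[[k]] <- structure(
      list(matrix_id = matrix_id, tf_name = tf_name, counts = counts),
      class = "jaspar_pfm")
  }
  names(out) <- map_chr(out, "matrix_id")
  out
}

#' @export
print.jaspar_pfm <- function(x, ...) {
  cat(sprintf("<jaspar_pfm> %s %s (L = %d)\n",
              x$matrix_id, x$tf_name, ncol(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Write position frequency matrices in JASPAR text format
#'
#' @param pfms A list of `jaspar_pfm` objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar_pfm <- function(pfms, path) {
  if (inherits(pfms, "jaspar_pfm")) pfms <- list(pfms)
  lines <- unlist(map(pfms, function(p) {
    c(sprintf(">%s %s", p$matrix_id, p$tf_name),
      map_chr(DNA_BASES, function(b) {
        sprintf("%s [ %s ]", b, paste(format(p$counts[b, ], trim = TRUE),
                                      collapse = " "))
      }))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Download JASPAR CORE matrices (network required)
#'
#' Fetches individual matrices from the JASPAR web API and stores them as
#' a single JASPAR text file readable with [read_jaspar_pfm()]. Intended
#' as a one-time step on a networked machine; all downstream analysis
#' reads the local file.
#'
#' @param ids Character vector of matrix ids, e.g. `"MA0018.2"`.
#' @param path Output file path.
#' @param base_url JASPAR API endpoint.
#' @return `path`, invisibly.
#' @export
jaspar_fetch <- function(ids, path,
                         base_url = "https://jaspar.elixir.no/api/v1/matrix") {
  blocks <- map_chr(ids, function(id) {
    url <- sprintf("%s/%s.jaspar", base_url, id)
    paste(readLines(url, warn = FALSE), collapse = "\n")
  })
  writeLines(paste(blocks, collapse = "\n"), path)
  invisible(path)
}

#' Read a feature-by-sample count matrix
#'
#' First column feature id, remaining columns one per sample. When a
#' sample table is given, columns are checked against it and reordered to
#' its sample order.
#'
#' @param path Path to a TSV with a header row.
#' @param samples Optional sample table (see [sample_table()]).
#' @return A numeric matrix (features x samples) with feature row names.
#' @export
read_count_matrix <- function(path, samples = NULL) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicated feature id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  m <- suppressWarnings(
    matrix(as.numeric(as.matrix(raw[-1])), nrow = nrow(raw),
           dimnames = list(NULL, names(raw)[-1])))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    abort(sprintf(
      "non-numeric or missing cell in count matrix (first at row %d, column %s)",
      bad[1, 1], colnames(m)[bad[1, 2]]))
  }
  rownames(m) <- ids
  if (!is.null(samples)) {
    samples <- sample_table(samples)
    miss <- setdiff(samples$sample_id, colnames(m))
    if (length(miss) > 0) {
      abort(paste0("sample(s) missing from matrix: ",
                   paste(miss, collapse = ", ")))
    }
    m <- m[, samples$sample_id, drop = FALSE]
  }
  m
}

#' Write a count matrix as TSV
#'
#' @param m A numeric matrix with feature row names.
#' @param path Output path.
#' @param id_col Name for the feature id column.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path, id_col = "feature_id") {
  out <- as_tibble(m, rownames = id_col)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a sample table from TSV
#'
#' @param path Path to a TSV with columns `sample_id`, `group` and
#'   optionally `subgroup`, `pair_id`.
#' @return A validated sample table tibble.
#' @export
read_sample_table <- function(path) {
  sample_table(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' Read sequences from a FASTA file
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
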