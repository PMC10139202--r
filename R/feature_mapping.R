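#' Derive intronic intervals of gene models
#'
#' Introns are the gaps between consecutive exons of a transcript; a
#' single-exon transcript has none. Coordinates stay 0-based half-open.
#'
#' @param genes A gene table (see [read_gene_table()]).
#' @return A tibble with one row per intron: `gene_id`, `tx_id`, `chrom`,
#'   `strand`, `start`, `end`.
#' @export
derive_introns <- function(genes) {
  genes <- validate_gene_table(genes)
  map_dfr(seq_len(nrow(genes)), function(i) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    if (length(es) < 2) {
      return(tibble(gene_id = character(), tx_id = character(),
                    chrom = character(), strand = character(),
                    start = integer(), end = integer()))
    }
    tibble(gene_id = genes$gene_id[i], tx_id = genes$tx_id[i],
           chrom = genes$chrom[i], strand = genes$strand[i],
           start = ee[-length(ee)], end = es[-1])
  })
}

#' Upstream annulus of a transcription start site
#'
#' The interval of positions whose distance upstream of the TSS lies in
#' `[near, far)`, strand-aware and clipped at zero: on the plus strand
#' `[tss - far, tss - near)`, on the minus strand `[tss + near, tss + far)`.
#'
#' @param genes A gene table.
#' @param near,far Distance bounds in bp, `0 <= near < far`.
#' @return A tibble with one row per transcript: `gene_id`, `tx_id`,
#'   `chrom`, `strand`, `tss`, `start`, `end`.
#' @export
upstream_annulus <- function(genes, near, far) {
  check_that(near >= 0 && near < far, "need 0 <= near < far")
  genes <- validate_gene_table(genes)
  start <- ifelse(genes$strand == "+", pmax(0L, genes$tss - far),
                  genes$tss + near)
  end <- ifelse(genes$strand == "+", pmax(0L, genes$tss - near),
                genes$tss + far)
  tibble(gene_id = genes$gene_id, tx_id = genes$tx_id, chrom = genes$chrom,
         strand = genes$strand, tss = genes$tss,
         start = as.integer(start), end = as.integer(end))
}

# Classify one set of (TE, transcript) candidate pairs.
# Precedence per transcript: exon > intron > up1k > up10k > up50k, with the
# three upstream shells decided by the minimum TE-edge-to-TSS distance.
classify_pairs <- function(pairs, genes) {
  if (nrow(pairs) == 0) {
    return(tibble(te_id = character(), gene_id = character(),
                  tx_id = character(), class = character(),
                  tss_distance = integer()))
  }
  gi <- match(pairs$tx_id, genes$tx_id)
  exon_hit <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    es <- genes$exon_starts[[gi[k]]]
    ee <- genes$exon_ends[[gi[k]]]
    exon_hit[k] <- any(pairs$te_start[k] < ee & pairs$te_end[k] > es)
  }
  span_hit <- pairs$te_start < genes$tx_end[gi] & pairs$te_end > genes$tx_start[gi]
  plus <- genes$strand[gi] == "+"
  updist <- ifelse(plus, genes$tss[gi] - pairs$te_end,
                   pairs$te_start - genes$tss[gi])
  cls <- case_when(
    exon_hit ~ "exon",
    span_hit ~ "intron",
    updist >= 0 & updist <= 1000 ~ "up1k",
    updist > 1000 & updist <= 10000 ~ "up10k",
    updist > 10000 & updist <= 50000 ~ "up50k",
    TRUE ~ NA_character_
  )
  tibble(te_id = pairs$te_id, gene_id = genes$gene_id[gi],
         tx_id = pairs$tx_id, class = cls,
         tss_distance = as.integer(ifelse(span_hit | exon_hit, 0L,
                                          pmax(updist, 0L)))) |>
    filter(!is.na(.data$class))
}

#' Assign TE loci to gene feature classes
#'
#' Classifies each TE locus relative to each gene into the five disjoint
#' feature classes: `exon`, `intron`, and the upstream annuli `up1k`
#' (0-1 kb], `up10k` (1-10 kb], `up50k` (10-50 kb]. Per (TE, transcript)
#' exactly one class is assigned, by precedence exon > intron > upstream,
#' with a TE spanning a shell boundary resolved by its minimum edge-to-TSS
#' distance. Per (TE, gene) the classes of all transcripts are unioned,
#' which is how combinations such as "intron + up50k" arise. TEs matching
#' no gene are omitted; downstream regions are ignored.
#'
#' @param tes A tibble of TE loci (see [read_bed()]): `chrom`, `start`,
#'   `end`, `id`, and optionally `strand`, `family`, `subfamily`.
#' @param genes A gene table (see [read_gene_table()]).
#' @param level `"gene"` (default; classes unioned across transcripts,
#'   comma-joined) or `"transcript"` (one class per (TE, transcript)).
#' @return For `level = "gene"`: a tibble `te_id`, `gene_id`, `classes`
#'   (comma-joined in precedence order), `min_tss_distance` (0 when the TE
#'   overlaps the gene). For `level = "transcript"`: `te_id`, `gene_id`,
#'   `tx_id`, `class`, `tss_distance`.
#' @export
assign_features <- function(tes, genes, level = c("gene", "transcript")) {
  level <- match.arg(level)
  genes <- validate_gene_table(genes)
  tes <- as_tibble(tes)
  check_that(all(c("chrom", "start", "end", "id") %in% names(tes)),
             "TE table needs chrom, start, end, id columns")
  orphan <- setdiff(unique(tes$chrom), unique(genes$chrom))
  if (length(orphan) > 0) {
    warn(paste0("TE chromosome(s) absent from gene table: ",
                paste(orphan, collapse = ", ")))
  }
  # candidate pairs: TE overlapping the transcript span extended 50 kb on
  # the upstream side
  ext_start <- ifelse(genes$strand == "+", pmax(0L, genes$tx_start - 50000L),
                      genes$tx_start)
  ext_end <- ifelse(genes$strand == "+", genes$tx_end, genes$tx_end + 50000L)
  pairs <- map_dfr(intersect(unique(tes$chrom), unique(genes$chrom)),
                   function(ch) {
    ti <- which(tes$chrom == ch)
    gj <- which(genes$chrom == ch)
    hits <- which(outer(tes$start[ti], ext_end[gj], "<") &
                    outer(tes$end[ti], ext_start[gj], ">"),
                  arr.ind = TRUE)
    tibble(te_id = tes$id[ti][hits[, 1]],
           te_start = tes$start[ti][hits[, 1]],
           te_end = tes$end[ti][hits[, 1]],
           tx_id = genes$tx_id[gj][hits[, 2]])
  })
  tx_level <- classify_pairs(pairs, genes)
  if (level == "transcript") return(arrange(tx_level, .data$te_id, .data$tx_id))
  if (nrow(tx_level) == 0) {
    return(tibble(te_id = character(), gene_id = character(),
                  classes = character(), min_tss_distance = integer()))
  }
  tx_level |>
    group_by(.data$te_id, .data$gene_id) |>
    summarise(
      classes = paste(FEATURE_CLASSES[sort(unique(match(.data$class,
                                                        FEATURE_CLASSES)))],
                      collapse = ","),
      min_tss_distance = min(.data$tss_distance),
      .groups = "drop") |>
    arrange(.data$te_id, .data$gene_id)
}

#' Summarise feature-class assignments
#'
#' Counts (TE, gene, class) occurrences per feature class - the "position"
#' tally whose per-class counts sum to the total because the classes are
#' disjoint annuli - plus the number of distinct genes per class.
#'
#' @param assignments Gene-level assignments from [assign_features()].
#' @return A tibble with one row per feature class (`class`,
#'   `n_positions`, `n_genes`) plus a leading `all` row with the totals.
#' @export
summarize_assignments <- function(assignments) {
  long <- assignments |>
    mutate(class = strsplit(.data$classes, ",", fixed = TRUE)) |>
    tidyr::unnest("class")
  per_class <- map_dfr(FEATURE_CLASSES, function(cl) {
    sub <- filter(long, .data$class == cl)
    tibble(class = cl, n_positions = nrow(sub),
           n_genes = n_distinct(sub$gene_id))
  })
  bind_rows(
    tibble(class = "all", n_positions = sum(per_class$n_positions),
           n_genes = n_distinct(long$gene_id)),
    per_class)
}
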