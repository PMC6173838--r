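# Syntenic gene-loss detection: a reference gene is called lost in the
# query when its nearest flanking genes with query orthologs are adjacent
# on a single query scaffold, leaving no room for an ortholog of the
# target between them.

# Map reference genes to their query orthologs.  Two assignment dialects
# are accepted: gene mode, where subject_seq_id is itself a reference gene
# ID, and coordinate mode, where subjects are reference chromosomes and
# the subject midpoint is located within a reference gene span.  When one
# reference gene attracts several query genes, the highest bitscore wins
# (ties to the lexicographically smallest query).
map_ref_orthologs <- function(ref_annotation, assignments) {
  n <- nrow(assignments)
  ref_gene <- rep(NA_character_, n)
  if (n == 0L) {
    return(data.frame(ref_gene_id = character(), query_gene_id = character(),
                      stringsAsFactors = FALSE))
  }
  gene_mode <- all(assignments$subject_seq_id %in% ref_annotation$gene_id)
  if (gene_mode) {
    ref_gene <- assignments$subject_seq_id
  } else {
    for (chrom in unique(assignments$subject_seq_id)) {
      genes <- ref_annotation[ref_annotation$seq_id == chrom, , drop = FALSE]
      sel <- which(assignments$subject_seq_id == chrom)
      if (nrow(genes) == 0L || length(sel) == 0L) next
      pos <- assignments$subject_midpoint[sel]
      k <- findInterval(pos, genes$start)
      inside <- k >= 1L & pos < genes$end[pmax(k, 1L)]
      ref_gene[sel[inside]] <- genes$gene_id[k[inside]]
    }
  }
  ok <- !is.na(ref_gene)
  pairs <- data.frame(
    ref_gene_id = ref_gene[ok],
    query_gene_id = assignments$query_gene_id[ok],
    bitscore = assignments$bitscore[ok],
    stringsAsFactors = FALSE
  )
  o <- order(pairs$ref_gene_id, -pairs$bitscore, pairs$query_gene_id,
             method = "radix")
  pairs <- pairs[o, , drop = FALSE]
  pairs <- pairs[!duplicated(pairs$ref_gene_id), c("ref_gene_id", "query_gene_id"),
                 drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

# Accepts any sequence-level ordering (lexicographic or karyotype order)
# but requires each sequence's rows to be contiguous and sorted by start.
assert_sorted_annotation <- function(ann, what) {
  r <- rle(ann$seq_id)
  if (anyDuplicated(r$values)) {
    stop(sprintf("%s annotation is not grouped by seq_id", what))
  }
  if (any(vapply(split(ann$start, factor(ann$seq_id, levels = r$values)),
                 is.unsorted, logical(1)))) {
    stop(sprintf("%s annotation is not sorted by start within seq_id", what))
  }
  invisible(ann)
}

#' Detect syntenic gene losses
#'
#' For every reference gene with no query ortholog, the nearest flanking
#' genes with orthologs are sought within `max_flank_scan` genes on each
#' side along the reference chromosome.  If both flank orthologs lie on
#' one query scaffold with at most `max_intervening` unrelated query
#' genes between them, the target is called a `syntenic_loss` and the
#' query intergenic interval between the inner edges of the two flank
#' orthologs is reported (0-based half-open) so residual-similarity
#' scans can be run on it externally.  Flank orthologs on different
#' scaffolds, or separated by more than `max_intervening` query genes,
#' give `unresolved_split_flanks`; a missing flank within scan range
#' gives `unresolved_flank_missing`.  A run of k adjacent lost genes
#' produces k calls sharing one interval.
#'
#' "Absent ortholog" means absent from the assignment map; no residual
#' sequence similarity is examined here.
#'
#' @param ref_annotation Reference gene annotation, sorted by
#'   `(seq_id, start)`.
#' @param query_annotation Query (scaffolded) gene annotation, sorted
#'   the same way.
#' @param assignments Per-gene assignments from [best_hits()], either
#'   against reference chromosomes (subject midpoints are located within
#'   reference gene spans) or directly against reference gene IDs.
#' @param max_flank_scan Genes scanned on each side for a flank with an
#'   ortholog (default 3).
#' @param max_intervening Maximum unrelated query genes allowed between
#'   the flank orthologs (default 0 = strict adjacency).
#' @return A data.frame with one row per candidate lost gene:
#'   `ref_gene_id`, `ref_chrom`, `left_flank_id`, `right_flank_id`,
#'   `query_scaffold`, `interval_start`, `interval_end`, `interval_len`,
#'   `n_intervening_query_genes`, `status`.
#' @export
detect_losses <- function(ref_annotation, query_annotation, assignments,
                          max_flank_scan = 3L, max_intervening = 0L) {
  assert_sorted_annotation(ref_annotation, "reference")
  assert_sorted_annotation(query_annotation, "query")

  pairs <- map_ref_orthologs(ref_annotation, assignments)
  q_of_ref <- stats::setNames(pairs$query_gene_id, pairs$ref_gene_id)

  q_scaf <- stats::setNames(query_annotation$seq_id, query_annotation$gene_id)
  q_start <- stats::setNames(query_annotation$start, query_annotation$gene_id)
  q_end <- stats::setNames(query_annotation$end, query_annotation$gene_id)
  q_rank <- stats::setNames(
    stats::ave(seq_len(nrow(query_annotation)), query_annotation$seq_id,
               FUN = seq_along),
    query_annotation$gene_id
  )

  calls <- list()
  for (chrom in unique(ref_annotation$seq_id)) {
    genes <- ref_annotation$gene_id[ref_annotation$seq_id == chrom]
    has_orth <- genes %in% pairs$ref_gene_id
    if (all(has_orth)) next
    r <- rle(has_orth)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (seg in which(!r$values)) {
      i <- starts[seg]; j <- ends[seg]
      left_rng <- seq(i - 1L, by = -1L,
                      length.out = min(max_flank_scan, i - 1L))
      right_rng <- seq(j + 1L, by = 1L,
                       length.out = min(max_flank_scan, length(genes) - j))
      left <- left_rng[has_orth[left_rng]][1L]
      right <- right_rng[has_orth[right_rng]][1L]

      run_genes <- genes[i:j]
      if (is.na(left) || is.na(right)) {
        calls[[length(calls) + 1L]] <- data.frame(
          ref_gene_id = run_genes, ref_chrom = chrom,
          left_flank_id = if (is.na(left)) NA_character_ else genes[left],
          right_flank_id = if (is.na(right)) NA_character_ else genes[right],
          query_scaffold = NA_character_, interval_start = NA_real_,
          interval_end = NA_real_, interval_len = NA_real_,
          n_intervening_query_genes = NA_integer_,
          status = "unresolved_flank_missing", stringsAsFactors = FALSE
        )
        next
      }

      qa <- q_of_ref[[genes[left]]]
      qb <- q_of_ref[[genes[right]]]
      if (q_scaf[[qa]] != q_scaf[[qb]]) {
        status <- "unresolved_split_flanks"
        scaf <- NA_character_; s <- NA_real_; e <- NA_real_
        n_iv <- NA_integer_
      } else {
        n_iv <- abs(q_rank[[qb]] - q_rank[[qa]]) - 1L
        if (n_iv <= max_intervening) {
          status <- "syntenic_loss"
          scaf <- q_scaf[[qa]]
          lo <- if (q_start[[qa]] <= q_start[[qb]]) qa else qb
          hi <- if (identical(lo, qa)) qb else qa
          s <- q_end[[lo]]; e <- q_start[[hi]]
          if (e < s) s <- e
        } else {
          # flanks on one scaffold but not adjacent: reported as split
          status <- "unresolved_split_flanks"
          scaf <- q_scaf[[qa]]; s <- NA_real_; e <- NA_real_
        }
      }
      calls[[length(calls) + 1L]] <- data.frame(
        ref_gene_id = run_genes, ref_chrom = chrom,
        left_flank_id = genes[left], right_flank_id = genes[right],
        query_scaffold = scaf, interval_start = s, interval_end = e,
        interval_len = if (is.na(s)) NA_real_ else e - s,
        n_intervening_query_genes = n_iv, status = status,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(calls) == 0L) {
    return(data.frame(
      ref_gene_id = character(), ref_chrom = character(),
      left_flank_id = character(), right_flank_id = character(),
      query_scaffold = character(), interval_start = numeric(),
      interval_end = numeric(), interval_len = numeric(),
      n_intervening_query_genes = integer(), status = character(),
      stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
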