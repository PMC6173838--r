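# Scaffold-to-chromosome anchoring by majority gene vote, with the strict
# better-than-50% conserved/rearranged classification and the genome-wide
# bp summary.

#' Anchor scaffolds to reference chromosomes by majority gene vote
#'
#' For each scaffold at least `min_len_bp` long, the chromosome
#' assignments of its genes are tallied as votes.  The scaffold is
#' anchored to the chromosome with the most votes (ties broken to the
#' lexicographically smallest chromosome and flagged `ambiguous`).  A
#' scaffold whose top chromosome collects strictly more than 50% of the
#' votes is classified `conserved` (hypothesized to descend from a
#' common ancestral chromosome); otherwise it is `rearranged` (a less
#' conserved, inter-chromosomally rearranged region).  Exactly 50% is
#' rearranged: the conserved criterion is strictly "better than 50%".
#' Scaffolds with genes but no assignments are `unplaced`.
#'
#' @param assignments Per-gene assignments from [best_hits()] (subjects
#'   are reference chromosomes).
#' @param annotation Gene annotation of the scaffolded genome, as from
#'   [read_gff3_genes()].  Every assigned gene must appear here.
#' @param lengths Scaffold length table, as from [read_lengths()]; must
#'   cover every scaffold in `annotation`.
#' @param min_len_bp Minimum scaffold length to call (default 1 Mb);
#'   shorter scaffolds are reported in the `"excluded"` attribute of the
#'   result.  Set 0 to call everything.
#' @param denominator Vote denominator for the 50% rule:
#'   `"hit_genes"` (genes with an assignment; default) or
#'   `"all_genes"` (all annotated genes on the scaffold).
#' @return A data.frame of class `anchor_calls`, one row per called
#'   scaffold, sorted by `scaffold_id`: `scaffold_id`, `scaffold_len`,
#'   `n_genes`, `n_hit_genes`, `assigned_chrom` (NA when unplaced),
#'   `top_fraction`, `klass` (`conserved`/`rearranged`/`unplaced`),
#'   `ambiguous`, and a list column `votes` of named per-chromosome gene
#'   counts.  Attribute `"excluded"` holds the sub-threshold scaffolds.
#' @export
anchor_scaffolds <- function(assignments, annotation, lengths,
                             min_len_bp = 1e6,
                             denominator = c("hit_genes", "all_genes")) {
  denominator <- match.arg(denominator)
  missing_len <- setdiff(annotation$seq_id, lengths$seq_id)
  if (length(missing_len)) {
    stop(sprintf("scaffold '%s' present in annotation but missing from lengths",
                 missing_len[1L]))
  }
  orphan <- setdiff(assignments$query_gene_id, annotation$gene_id)
  if (length(orphan)) {
    stop(sprintf("assigned gene '%s' not found in the annotation", orphan[1L]))
  }

  scaffolds <- sort(unique(annotation$seq_id))
  scaf_len <- lengths$length_bp[match(scaffolds, lengths$seq_id)]
  n_genes <- as.integer(table(factor(annotation$seq_id, levels = scaffolds)))

  gene_scaf <- annotation$seq_id[match(assignments$query_gene_id,
                                       annotation$gene_id)]
  vote_split <- split(assignments$subject_seq_id,
                      factor(gene_scaf, levels = scaffolds))

  votes <- vector("list", length(scaffolds))
  assigned <- rep(NA_character_, length(scaffolds))
  top_fraction <- rep(NA_real_, length(scaffolds))
  ambiguous <- rep(FALSE, length(scaffolds))
  n_hit <- integer(length(scaffolds))
  klass <- character(length(scaffolds))

  for (i in seq_along(scaffolds)) {
    v <- table(vote_split[[i]])
    if (length(v)) v <- v[order(names(v), method = "radix")]
    votes[[i]] <- stats::setNames(as.integer(v), names(v))
    n_hit[i] <- sum(v)
    if (n_hit[i] == 0L) {
      klass[i] <- "unplaced"
      next
    }
    top <- names(v)[v == max(v)]
    assigned[i] <- sort(top)[1L]
    ambiguous[i] <- length(top) > 1L
    denom <- if (denominator == "hit_genes") n_hit[i] else n_genes[i]
    top_fraction[i] <- max(v) / denom
    klass[i] <- if (top_fraction[i] > 0.5) "conserved" else "rearranged"
  }

  calls <- data.frame(
    scaffold_id = scaffolds, scaffold_len = scaf_len,
    n_genes = n_genes, n_hit_genes = n_hit,
    assigned_chrom = assigned, top_fraction = top_fraction,
    klass = klass, ambiguous = ambiguous, stringsAsFactors = FALSE
  )
  calls$votes <- I(votes)

  eligible <- calls$scaffold_len >= min_len_bp
  out <- calls[eligible, , drop = FALSE]
  rownames(out) <- NULL
  excl <- calls[!eligible, c("scaffold_id", "scaffold_len", "n_genes"),
                drop = FALSE]
  rownames(excl) <- NULL
  attr(out, "excluded") <- excl
  class(out) <- c("anchor_calls", "data.frame")
  out
}

# Integer percent shares by the largest-remainder method: floors of the raw
# percentages, with the remainder units going to the largest fractional
# parts (ties resolved by name order for determinism).
largest_remainder <- function(x, total = 100L) {
  if (sum(x) == 0) return(stats::setNames(integer(length(x)), names(x)))
  raw <- x / sum(x) * total
  fl <- floor(raw)
  rem <- as.integer(round(total - sum(fl)))
  if (rem > 0L) {
    o <- order(-(raw - fl), names(x), method = "radix")
    fl[o[seq_len(rem)]] <- fl[o[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(fl), names(x))
}

#' Summarize anchor calls into genome-wide bp shares
#'
#' Totals scaffold counts and bp per class and computes integer percent
#' shares of the classified (conserved + rearranged) bp, rounded with
#' largest-remainder repair so the two shares sum to exactly 100.
#' Unplaced scaffolds contribute to `total_bp` but not to the two-class
#' percentage.
#'
#' @param calls An `anchor_calls` data.frame from [anchor_scaffolds()],
#'   or any data.frame with columns `scaffold_id`, `scaffold_len`,
#'   `klass`.
#' @return A list of class `anchor_summary`: `class_count`, `class_bp`
#'   (named by class), `share_pct` (integer percents for conserved and
#'   rearranged, summing to 100), `classified_bp`, `total_bp`.
#' @export
anchor_summary <- function(calls) {
  if (nrow(calls) == 0L) stop("nothing to summarize")
  lv <- c("conserved", "rearranged", "unplaced")
  kl <- factor(calls$klass, levels = lv)
  class_count <- stats::setNames(as.integer(table(kl)), lv)
  class_bp <- stats::setNames(
    as.numeric(tapply(calls$scaffold_len, kl, sum, default = 0)), lv)
  classified_bp <- class_bp[["conserved"]] + class_bp[["rearranged"]]
  share_pct <- largest_remainder(
    c(conserved = class_bp[["conserved"]], rearranged = class_bp[["rearranged"]])
  )
  structure(list(
    class_count = class_count, class_bp = class_bp, share_pct = share_pct,
    classified_bp = classified_bp, total_bp = sum(calls$scaffold_len)
  ), class = "anchor_summary")
}

#' @export
print.anchor_summary <- function(x, ...) {
  cat("Anchoring summary\n")
  for (k in names(x$class_count)) {
    cat(sprintf("  %-10s %4d scaffolds  %12.0f bp", k, x$class_count[[k]],
                x$class_bp[[k]]))
    if (k %in% names(x$share_pct)) {
      cat(sprintf("  (%d%% of classified bp)", x$share_pct[[k]]))
    }
    cat("\n")
  }
  cat(sprintf("  total      %12.0f bp (classified %12.0f bp)\n",
              x$total_bp, x$classified_bp))
  invisible(x)
}
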