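# Order and orient anchored scaffolds into hypothetical chromosomes and
# emit them as AGP 2.1.

#' Order and orient anchored scaffolds along their chromosomes
#'
#' Within each target chromosome, scaffolds are ordered by the median
#' reference position (subject midpoint) of the genes voting for that
#' chromosome; ties put the longer scaffold first, then sort
#' lexicographically.  Orientation is `+` when the Spearman rank
#' correlation between gene order along the scaffold and subject
#' midpoint is >= 0 and `-` otherwise; the median (not the mean) makes
#' the placement robust to a minority of translocated genes.  Scaffolds
#' with fewer than two informative genes get `+` and
#' `low_confidence = TRUE`.
#'
#' @param calls `anchor_calls` from [anchor_scaffolds()]; only
#'   `conserved` and `rearranged` scaffolds are placed.
#' @param assignments Per-gene assignments from [best_hits()].
#' @param annotation Derived gene annotation.
#' @return A data.frame with one row per placed scaffold:
#'   `scaffold_id`, `target_chrom`, `order_index` (0-based, unique per
#'   chromosome), `orientation`, `median_subject_pos`,
#'   `orientation_support` (informative gene pairs), `low_confidence`,
#'   `scaffold_len`.
#' @export
place_scaffolds <- function(calls, assignments, annotation) {
  unknown <- setdiff(calls$scaffold_id, annotation$seq_id)
  if (length(unknown)) {
    stop(sprintf("anchor call references unknown scaffold '%s'", unknown[1L]))
  }
  placed <- calls[calls$klass %in% c("conserved", "rearranged"), ,
                  drop = FALSE]
  if (nrow(placed) == 0L) {
    return(data.frame(
      scaffold_id = character(), target_chrom = character(),
      order_index = integer(), orientation = character(),
      median_subject_pos = numeric(), orientation_support = integer(),
      low_confidence = logical(), scaffold_len = numeric(),
      stringsAsFactors = FALSE
    ))
  }

  gene_scaf <- annotation$seq_id[match(assignments$query_gene_id,
                                       annotation$gene_id)]
  gene_start <- annotation$start[match(assignments$query_gene_id,
                                       annotation$gene_id)]

  res <- lapply(seq_len(nrow(placed)), function(i) {
    sid <- placed$scaffold_id[i]
    chrom <- placed$assigned_chrom[i]
    sel <- which(gene_scaf == sid & assignments$subject_seq_id == chrom)
    mids <- assignments$subject_midpoint[sel]
    starts <- gene_start[sel]
    o <- order(starts)
    mids <- mids[o]; starts <- starts[o]
    n <- length(mids)
    # informative pairs: both scaffold position and subject midpoint differ
    # (scaffold starts are distinct, so only midpoint ties reduce the count)
    support <- if (n < 2L) 0L else {
      ties <- table(mids)
      as.integer(choose(n, 2) - sum(choose(ties, 2)))
    }
    if (n < 2L || support == 0L) {
      orientation <- "+"; low_conf <- TRUE
    } else {
      rho <- stats::cor(starts, mids, method = "spearman")
      orientation <- if (!is.na(rho) && rho < 0) "-" else "+"
      low_conf <- FALSE
    }
    data.frame(
      scaffold_id = sid, target_chrom = chrom,
      median_subject_pos = floor(stats::median(mids)),
      orientation = orientation, orientation_support = support,
      low_confidence = low_conf, scaffold_len = placed$scaffold_len[i],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)

  o <- order(out$target_chrom, out$median_subject_pos, -out$scaffold_len,
             out$scaffold_id, method = "radix")
  out <- out[o, , drop = FALSE]
  out$order_index <- stats::ave(seq_len(nrow(out)), out$target_chrom,
                                FUN = seq_along) - 1L
  out <- out[, c("scaffold_id", "target_chrom", "order_index", "orientation",
                 "median_subject_pos", "orientation_support",
                 "low_confidence", "scaffold_len")]
  rownames(out) <- NULL
  out
}

#' Emit hypothetical chromosomes as AGP rows
#'
#' Builds one AGP object `hypChr<chrom>` per target chromosome: `W` rows
#' for the placed scaffolds in `order_index` order (component
#' coordinates always `1..len`; reversal is carried by the orientation
#' column) separated by `U` gap rows of `gap_len` bp (gap_type
#' `scaffold`, linkage `no`, evidence `align_genus`).  The gap length is
#' a conventional placeholder, not a biological estimate.
#'
#' @param placements From [place_scaffolds()].
#' @param lengths Scaffold length table covering every placed scaffold.
#' @param gap_len Inter-scaffold gap length in bp (default 100).
#' @return An AGP data.frame in the layout of [read_agp()]; write it
#'   with [write_agp()].
#' @export
emit_agp <- function(placements, lengths, gap_len = 100L) {
  missing_len <- setdiff(placements$scaffold_id, lengths$seq_id)
  if (length(missing_len)) {
    stop(sprintf("no length for placed scaffold '%s'", missing_len[1L]))
  }
  objs <- list()
  for (chrom in sort(unique(placements$target_chrom))) {
    pl <- placements[placements$target_chrom == chrom, , drop = FALSE]
    if (anyDuplicated(pl$order_index)) {
      stop(sprintf("duplicate order_index on chromosome %s", chrom))
    }
    pl <- pl[order(pl$order_index), , drop = FALSE]
    object_id <- paste0("hypChr", sub("^chr", "", chrom))
    cursor <- 0L; part <- 0L
    rows <- list()
    for (j in seq_len(nrow(pl))) {
      if (j > 1L && gap_len > 0L) {
        part <- part + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          object_id = object_id, object_start = cursor + 1L,
          object_end = cursor + gap_len, part_number = part,
          component_type = "U", component_id = NA_character_,
          component_start = NA_integer_, component_end = NA_integer_,
          orientation = NA_character_, gap_length = as.integer(gap_len),
          gap_type = "scaffold", linkage = "no", evidence = "align_genus",
          stringsAsFactors = FALSE
        )
        cursor <- cursor + gap_len
      }
      len <- lengths$length_bp[match(pl$scaffold_id[j], lengths$seq_id)]
      part <- part + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        object_id = object_id, object_start = cursor + 1L,
        object_end = cursor + len, part_number = part,
        component_type = "W", component_id = pl$scaffold_id[j],
        component_start = 1L, component_end = as.integer(len),
        orientation = pl$orientation[j], gap_length = NA_integer_,
        gap_type = NA_character_, linkage = NA_character_,
        evidence = NA_character_, stringsAsFactors = FALSE
      )
      cursor <- cursor + as.integer(len)
    }
    objs[[chrom]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, objs)
  rownames(out) <- NULL
  validate_agp(out)
}
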