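# Reduce a raw hit table to one assignment per query gene (best hit, with
# optional reciprocal-best-hit flagging).

#' Best-hit assignment per query gene
#'
#' For each query gene the hit with the maximal bitscore is kept.  Ties
#' are broken by higher alignment length, then by the lexicographically
#' smallest subject ID; a query whose top bitscore is reached on more
#' than one distinct subject is flagged `ambiguous`.  Genes with no hits
#' are absent from the result.  The output is invariant under
#' permutation of the input rows.
#'
#' Multiple HSPs of one gene against one subject are by default
#' represented by their single best HSP; with `sum_hsps = TRUE` the
#' bitscores (and alignment lengths) of all HSPs per (query, subject)
#' pair are summed before ranking, and the coordinates of the pair's
#' best HSP are retained.
#'
#' @param hits A hit table as returned by [read_blast_tab()].
#' @param sum_hsps Sum HSP bitscores per (query, subject) pair before
#'   ranking (default `FALSE`).
#' @return A data.frame with one row per query gene: `query_gene_id`,
#'   `subject_seq_id`, `subject_midpoint` (0-based midpoint of the
#'   subject interval), `bitscore`, `aln_len`, `ambiguous`,
#'   `reciprocal` (`NA` until [reciprocal_filter()] is applied), sorted
#'   by `query_gene_id`.
#' @export
best_hits <- function(hits, sum_hsps = FALSE) {
  empty <- data.frame(
    query_gene_id = character(), subject_seq_id = character(),
    subject_midpoint = numeric(), bitscore = numeric(), aln_len = integer(),
    ambiguous = logical(), reciprocal = logical(), stringsAsFactors = FALSE
  )
  if (nrow(hits) == 0L) return(empty)
  h <- hits

  if (isTRUE(sum_hsps)) {
    key <- paste(h$query_id, h$subject_id, sep = "\r")
    total_bs <- stats::ave(h$bitscore, key, FUN = sum)
    total_len <- stats::ave(h$aln_len, key, FUN = sum)
    # representative HSP per pair: the pair's best, same ranking key
    o <- order(key, -h$bitscore, -h$aln_len, method = "radix")
    h <- h[o, , drop = FALSE]
    total_bs <- total_bs[o]; total_len <- total_len[o]
    keep <- !duplicated(paste(h$query_id, h$subject_id, sep = "\r"))
    h <- h[keep, , drop = FALSE]
    h$bitscore <- total_bs[keep]
    h$aln_len <- as.integer(total_len[keep])
  }

  o <- order(h$query_id, -h$bitscore, -h$aln_len, h$subject_id,
             method = "radix")
  h <- h[o, , drop = FALSE]
  top <- h[!duplicated(h$query_id), , drop = FALSE]

  max_bs <- stats::ave(h$bitscore, h$query_id, FUN = max)
  at_max <- h[h$bitscore == max_bs, , drop = FALSE]
  n_subj <- tapply(at_max$subject_id, at_max$query_id,
                   function(s) length(unique(s)))
  ambiguous <- unname(n_subj[top$query_id] > 1L)

  mid <- (pmin(top$s_start, top$s_end) - 1L + pmax(top$s_start, top$s_end)) %/% 2L
  out <- data.frame(
    query_gene_id = top$query_id, subject_seq_id = top$subject_id,
    subject_midpoint = as.numeric(mid), bitscore = top$bitscore,
    aln_len = top$aln_len, ambiguous = ambiguous, reciprocal = NA,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$query_gene_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag reciprocal best hits
#'
#' Marks an assignment `reciprocal = TRUE` iff the forward best hit of
#' gene `g` is subject `s` and the reverse best hit of `s` is `g`.
#' Non-reciprocal assignments are retained, flagged `FALSE`.
#'
#' @param forward Assignments from [best_hits()] on the forward hit
#'   table (query genes vs subject genes).
#' @param reverse Assignments from [best_hits()] on the reverse table,
#'   with the same semantics (subject genes as queries).
#' @return `forward` with the `reciprocal` column filled in.
#' @export
reciprocal_filter <- function(forward, reverse) {
  ridx <- match(forward$subject_seq_id, reverse$query_gene_id)
  forward$reciprocal <- !is.na(ridx) &
    reverse$subject_seq_id[ridx] == forward$query_gene_id
  forward
}
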