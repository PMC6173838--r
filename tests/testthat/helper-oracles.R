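# Independent brute-force oracles and small-fixture generators used across
# the suite.  Each oracle is a direct, unoptimized restatement of the rule
# it checks, sharing no code with the implementation.

# -- best-hit oracle: literal max-scan per query ----------------------------
oracle_best_hits <- function(hits) {
  out <- list()
  for (q in sort(unique(hits$query_id))) {
    h <- hits[hits$query_id == q, , drop = FALSE]
    best <- NULL
    for (i in seq_len(nrow(h))) {
      cand <- h[i, ]
      if (is.null(best) ||
          cand$bitscore > best$bitscore ||
          (cand$bitscore == best$bitscore && cand$aln_len > best$aln_len) ||
          (cand$bitscore == best$bitscore && cand$aln_len == best$aln_len &&
           cand$subject_id < best$subject_id)) {
        best <- cand
      }
    }
    top_subjects <- unique(h$subject_id[h$bitscore == max(h$bitscore)])
    out[[q]] <- data.frame(
      query_gene_id = q, subject_seq_id = best$subject_id,
      ambiguous = length(top_subjects) > 1, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

# -- anchoring oracle: recount votes straight from the hit table ------------
oracle_anchor_klass <- function(hits, annotation, lengths, min_len_bp = 0) {
  ora <- oracle_best_hits(hits)
  res <- list()
  for (s in sort(unique(annotation$seq_id))) {
    len <- lengths$length_bp[lengths$seq_id == s]
    if (len < min_len_bp) next
    genes <- annotation$gene_id[annotation$seq_id == s]
    subj <- ora$subject_seq_id[ora$query_gene_id %in% genes]
    if (length(subj) == 0L) {
      res[[s]] <- data.frame(scaffold_id = s, assigned_chrom = NA_character_,
                             klass = "unplaced", stringsAsFactors = FALSE)
      next
    }
    tab <- table(subj)
    winners <- sort(names(tab)[tab == max(tab)])
    klass <- if (max(tab) / length(subj) > 0.5) "conserved" else "rearranged"
    res[[s]] <- data.frame(scaffold_id = s, assigned_chrom = winners[1],
                           klass = klass, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# -- Dollo oracle: exhaustive minimization over loss placements -------------
# Enumerates every subset of branches (edges plus a virtual root branch)
# and keeps the smallest subset that blacks out exactly the absent leaves.
oracle_dollo_gene <- function(tree, absent_tips) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nodes <- seq_len(ntip + tree$Nnode)   # candidate loss branches, by child node
  parent <- integer(ntip + tree$Nnode)
  for (k in seq_len(nrow(tree$edge))) parent[tree$edge[k, 2]] <- tree$edge[k, 1]

  path_to_root <- function(tip) {
    p <- tip
    while (p != root) {
      p <- parent[p]
      tip <- c(tip, p)
    }
    tip
  }
  absent_idx <- match(absent_tips, tree$tip.label)
  best <- NULL
  for (size in 0:length(nodes)) {
    combos <- utils::combn(nodes, size, simplify = FALSE)
    for (set in combos) {
      blacked <- vapply(seq_len(ntip),
                        function(t) any(path_to_root(t) %in% set), logical(1))
      if (setequal(which(blacked), absent_idx)) {
        best <- set
        break
      }
    }
    if (!is.null(best)) break
  }
  best
}

# label a node set the same way the package does (for comparisons)
oracle_node_labels <- function(tree, nodes) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent <- integer(ntip + tree$Nnode)
  for (k in seq_len(nrow(tree$edge))) parent[tree$edge[k, 2]] <- tree$edge[k, 1]
  tips_below <- function(nd) {
    keep <- vapply(seq_len(ntip), function(t) {
      p <- t
      repeat {
        if (p == nd) return(TRUE)
        if (p == root) return(FALSE)
        p <- parent[p]
      }
    }, logical(1))
    tree$tip.label[keep]
  }
  vapply(nodes, function(nd) {
    if (nd <= ntip) return(tree$tip.label[nd])
    nl <- if (!is.null(tree$node.label)) tree$node.label[nd - ntip] else ""
    if (!is.na(nl) && nzchar(nl)) return(nl)
    paste(sort(tips_below(nd)), collapse = "|")
  }, character(1))
}

# -- generators -------------------------------------------------------------
random_hits <- function(n, n_genes, n_chroms, seed) {
  set.seed(seed)
  data.frame(
    query_id = sprintf("g%03d", sample.int(n_genes, n, replace = TRUE)),
    subject_id = sprintf("chr%d", sample.int(n_chroms, n, replace = TRUE)),
    pct_identity = round(runif(n, 80, 100), 1),
    aln_len = sample(100:2000, n, replace = TRUE),
    mismatches = sample(0:50, n, replace = TRUE),
    gap_opens = sample(0:5, n, replace = TRUE),
    q_start = 1L, q_end = 100L,
    s_start = sample.int(1e6, n, replace = TRUE),
    s_end = sample.int(1e6, n, replace = TRUE) + 100L,
    evalue = signif(10^runif(n, -100, -5), 3),
    bitscore = sample(seq(50, 500, by = 10), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

random_presence_matrix <- function(n_genes, taxa, seed) {
  set.seed(seed)
  m <- matrix(sample(c("present", "pseudogene", "absent"),
                     n_genes * length(taxa), replace = TRUE,
                     prob = c(0.6, 0.15, 0.25)),
              nrow = n_genes,
              dimnames = list(sprintf("G%02d", seq_len(n_genes)), taxa))
  m
}

# tiny hand-buildable annotation
make_genes <- function(ids, seq_id, starts, len = 100L,
                       biotype = "protein_coding") {
  data.frame(gene_id = ids, seq_id = seq_id, start = starts,
             end = starts + len, strand = "+", biotype = biotype,
             stringsAsFactors = FALSE)
}

# minimal hit row(s)
make_hits <- function(query, subject, bitscore, aln_len = 100L,
                      s_start = 1L, s_end = 100L) {
  if (length(query) == 0L && length(subject) == 0L) {
    return(data.frame(
      query_id = character(), subject_id = character(),
      pct_identity = numeric(), aln_len = integer(), mismatches = integer(),
      gap_opens = integer(), q_start = integer(), q_end = integer(),
      s_start = integer(), s_end = integer(), evalue = numeric(),
      bitscore = numeric(), stringsAsFactors = FALSE
    ))
  }
  n <- max(length(query), length(subject), length(bitscore))
  data.frame(
    query_id = rep_len(query, n), subject_id = rep_len(subject, n),
    pct_identity = 95, aln_len = rep_len(aln_len, n), mismatches = 0L,
    gap_opens = 0L, q_start = 1L, q_end = 100L,
    s_start = rep_len(s_start, n), s_end = rep_len(s_end, n),
    evalue = 1e-50, bitscore = rep_len(bitscore, n), stringsAsFactors = FALSE
  )
}

zero_noise_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, hit_miss_rate = 0, spurious_hit_rate = 0,
             paralog_tie_rate = 0, ...)
}
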