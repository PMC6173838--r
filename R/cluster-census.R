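# Gene-family census on a rooted species tree: Dollo-parsimony assignment
# of gene losses to branches from a presence/pseudogene/absence matrix,
# and per-taxon intact-gene counts.

PRESENCE_STATES <- c("present", "pseudogene", "absent")

#' Read a gene x taxon presence/pseudogene/absence matrix
#'
#' @param path TSV with a header row of taxon names, one row per gene
#'   (first column the gene label), cells one of `P` (present),
#'   `Ψ`/`PS` (pseudogene) or `A` (absent); the long forms
#'   `present`/`pseudogene`/`absent` are also accepted.
#' @return A character matrix with values
#'   `present`/`pseudogene`/`absent`, gene labels as rownames and taxa
#'   as colnames.
#' @export
read_presence_matrix <- function(path) {
  x <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                         check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(x) < 2L) stop("presence matrix needs a gene column plus >= 1 taxon")
  genes <- x[[1L]]
  if (anyDuplicated(genes)) {
    stop(sprintf("duplicate gene label '%s' in presence matrix",
                 genes[duplicated(genes)][1L]))
  }
  m <- as.matrix(x[, -1L, drop = FALSE])
  rownames(m) <- genes
  decode <- c("P" = "present", "Ψ" = "pseudogene", "PS" = "pseudogene",
              "A" = "absent", "present" = "present",
              "pseudogene" = "pseudogene", "absent" = "absent")
  v <- decode[trimws(m)]
  if (anyNA(v)) {
    bad <- trimws(m)[is.na(v)][1L]
    stop(sprintf("unrecognized presence state '%s'", bad))
  }
  matrix(v, nrow = nrow(m), dimnames = dimnames(m))
}

# Deterministic label for every node: tips keep their label; internal
# nodes use tree$node.label when present, otherwise the sorted tip labels
# of their clade joined with "|".
node_labels <- function(tree) {
  ntip <- length(tree$tip.label)
  labs <- character(ntip + tree$Nnode)
  labs[seq_len(ntip)] <- tree$tip.label
  clades <- clade_tips(tree)
  for (nd in (ntip + 1L):(ntip + tree$Nnode)) {
    nl <- if (!is.null(tree$node.label)) tree$node.label[nd - ntip] else ""
    labs[nd] <- if (!is.na(nl) && nzchar(nl)) nl else
      paste(sort(tree$tip.label[clades[[nd]]]), collapse = "|")
  }
  labs
}

# tip indices below each node (tips map to themselves)
clade_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  n_all <- ntip + tree$Nnode
  out <- vector("list", n_all)
  for (i in seq_len(ntip)) out[[i]] <- i
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1L]; ch <- edge[k, 2L]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

#' Dollo-parsimony assignment of gene losses to tree branches
#'
#' Assumes a single origin at the root (every gene present in the root
#' ancestor; gains are never inferred) and finds, for each gene, the
#' minimal set of branches whose loss separates exactly the taxa lacking
#' the gene from the root.  That minimal set is the set of maximal
#' clades whose leaves all lack the gene; a gene absent from every leaf
#' is assigned one loss on the root branch.  Pseudogene cells are mapped
#' before inference: under `as_absent` (default) a pseudogene counts as
#' lost, under `as_present` it counts as retained.
#'
#' Branches are named by their child node: tip labels for terminal
#' branches, internal node labels (or the sorted tip labels of the
#' clade joined with `|`) for internal branches, the root label for the
#' root.
#'
#' @param matrix A presence matrix as from [read_presence_matrix()].
#' @param tree A rooted `phylo` tree whose tip labels are exactly the
#'   matrix taxa.
#' @param pseudogene_mode `"as_absent"` (default) or `"as_present"`.
#' @return A list of class `dollo_losses`: `branch_losses` (named list,
#'   branch -> sorted gene labels lost on it), `gene_losses` (named
#'   list, gene -> branches), and `intact` (per-taxon intact counts
#'   under the same mode, from [intact_counts()]).
#' @export
dollo_losses <- function(matrix, tree,
                         pseudogene_mode = c("as_absent", "as_present")) {
  pseudogene_mode <- match.arg(pseudogene_mode)
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!setequal(colnames(matrix), tree$tip.label)) {
    stop("matrix taxa and tree tip labels do not match")
  }
  if (!all(matrix %in% PRESENCE_STATES)) {
    stop("matrix cells must be present/pseudogene/absent")
  }

  absent_states <- if (pseudogene_mode == "as_absent") {
    c("absent", "pseudogene")
  } else {
    "absent"
  }

  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[edge[, 2L]] <- edge[, 1L]
  labs <- node_labels(tree)

  gene_losses <- vector("list", nrow(matrix))
  names(gene_losses) <- rownames(matrix)
  for (g in rownames(matrix)) {
    absent_tip <- matrix[g, tree$tip.label] %in% absent_states
    node_absent <- logical(ntip + tree$Nnode)
    node_absent[seq_len(ntip)] <- absent_tip
    all_absent <- rep(TRUE, ntip + tree$Nnode)
    all_absent[seq_len(ntip)] <- absent_tip
    # postorder: an internal node is all-absent iff every child is
    for (k in seq_len(nrow(edge))) {
      p <- edge[k, 1L]; ch <- edge[k, 2L]
      all_absent[p] <- all_absent[p] && all_absent[ch]
    }
    loss_nodes <- which(vapply(seq_len(ntip + tree$Nnode), function(nd) {
      all_absent[nd] && (nd == root || !all_absent[parent_of[nd]])
    }, logical(1)))
    gene_losses[[g]] <- sort(labs[loss_nodes])
  }

  branch_losses <- list()
  for (g in names(gene_losses)) {
    for (b in gene_losses[[g]]) {
      branch_losses[[b]] <- c(branch_losses[[b]], g)
    }
  }
  branch_losses <- lapply(branch_losses, sort)
  if (length(branch_losses)) {
    branch_losses <- branch_losses[order(names(branch_losses),
                                         method = "radix")]
  }

  structure(list(
    branch_losses = branch_losses,
    gene_losses = gene_losses,
    intact = intact_counts(matrix, pseudogene_mode)
  ), class = "dollo_losses")
}

#' Per-taxon intact gene counts
#'
#' Counts cells with state `present` per taxon; under `as_present` mode
#' pseudogenes count as intact too.
#'
#' @inheritParams dollo_losses
#' @return Named integer vector, one count per taxon.
#' @export
intact_counts <- function(matrix,
                          pseudogene_mode = c("as_absent", "as_present")) {
  pseudogene_mode <- match.arg(pseudogene_mode)
  keep <- if (pseudogene_mode == "as_present") {
    c("present", "pseudogene")
  } else {
    "present"
  }
  counts <- colSums(matrix(matrix %in% keep, nrow = nrow(matrix)))
  stats::setNames(as.integer(counts), colnames(matrix))
}

#' @export
print.dollo_losses <- function(x, ...) {
  cat("Dollo loss assignment\n")
  for (b in names(x$branch_losses)) {
    cat(sprintf("  %s: %s\n", b, paste(x$branch_losses[[b]], collapse = ", ")))
  }
  cat("Intact genes per taxon:\n")
  for (t in names(x$intact)) cat(sprintf("  %s: %d\n", t, x$intact[[t]]))
  invisible(x)
}
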