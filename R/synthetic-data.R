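# Genome-evolution simulator: a chromosome-level reference genome and a
# derived, scaffolded genome related to it by inter-chromosomal
# translocations, chromosome fission, gene loss/pseudogenization and
# fragmentation, plus a noisy hit table and full ground truth.

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# sample() without the length-1 surprise
resample <- function(x, n) x[sample.int(length(x), n)]

#' Simulation configuration
#'
#' Parameters of the genome-evolution simulator.  The defaults model the
#' study design this package targets: a 29-chromosome reference genome
#' (channel-catfish-like, n = 29) and a derived genome whose karyotype
#' differs by one fission (n = 30, striped-catfish-like), assembled only
#' to scaffold level.
#'
#' @param seed Integer seed; identical configs (including seed) produce
#'   byte-identical datasets.
#' @param n_chrom_ref Number of reference chromosomes (default 29).
#' @param genes_per_chrom Genes per reference chromosome (default 200).
#' @param gene_len_bp Gene model length in bp (default 2000).
#' @param intergenic_bp Intergenic spacer length in bp (default 8000).
#' @param n_translocations Number of reciprocal inter-chromosomal block
#'   exchanges applied to the derived genome.
#' @param translocation_block_genes Contiguous genes per exchanged block
#'   (default 10).
#' @param n_fissions Chromosome fissions at random intergenic points
#'   (default 1, modelling n = 29 vs n = 30).
#' @param n_losses Genes deleted outright from the derived genome.
#' @param n_pseudogenes Derived genes flipped to biotype `pseudogene`.
#' @param scaffold_mean_genes Mean genes per scaffold; scaffold gene
#'   counts are geometric with this mean and breakpoints fall only in
#'   intergenic space (default 25).
#' @param hit_miss_rate Probability a surviving derived gene has no hit
#'   in the hit table.
#' @param spurious_hit_rate Probability of an extra low-bitscore hit on a
#'   random chromosome.
#' @param paralog_tie_rate Probability of a second, equal-bitscore hit on
#'   a different chromosome (an unresolvable paralog tie).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chrom_ref = 29L, genes_per_chrom = 200L,
                       gene_len_bp = 2000L, intergenic_bp = 8000L,
                       n_translocations = 0L, translocation_block_genes = 10L,
                       n_fissions = 1L, n_losses = 0L, n_pseudogenes = 0L,
                       scaffold_mean_genes = 25L,
                       hit_miss_rate = 0.05, spurious_hit_rate = 0.02,
                       paralog_tie_rate = 0.01) {
  cfg <- list(
    seed = as.integer(seed), n_chrom_ref = as.integer(n_chrom_ref),
    genes_per_chrom = as.integer(genes_per_chrom),
    gene_len_bp = as.integer(gene_len_bp),
    intergenic_bp = as.integer(intergenic_bp),
    n_translocations = as.integer(n_translocations),
    translocation_block_genes = as.integer(translocation_block_genes),
    n_fissions = as.integer(n_fissions), n_losses = as.integer(n_losses),
    n_pseudogenes = as.integer(n_pseudogenes),
    scaffold_mean_genes = as.integer(scaffold_mean_genes),
    hit_miss_rate = hit_miss_rate, spurious_hit_rate = spurious_hit_rate,
    paralog_tie_rate = paralog_tie_rate
  )
  counts <- cfg[c("n_chrom_ref", "genes_per_chrom", "gene_len_bp",
                  "intergenic_bp", "n_translocations",
                  "translocation_block_genes", "n_fissions", "n_losses",
                  "n_pseudogenes", "scaffold_mean_genes")]
  if (any(vapply(counts, function(x) is.na(x) || x < 0L, logical(1)))) {
    stop("sim_config: counts must be non-negative integers")
  }
  if (cfg$n_chrom_ref < 1L || cfg$genes_per_chrom < 1L ||
      cfg$gene_len_bp < 1L || cfg$scaffold_mean_genes < 1L) {
    stop("sim_config: n_chrom_ref, genes_per_chrom, gene_len_bp and scaffold_mean_genes must be >= 1")
  }
  rates <- c(cfg$hit_miss_rate, cfg$spurious_hit_rate, cfg$paralog_tie_rate)
  if (any(is.na(rates) | rates < 0 | rates > 1)) {
    stop("sim_config: rates must lie in [0, 1]")
  }
  if (cfg$n_translocations * cfg$translocation_block_genes >
      cfg$n_chrom_ref * cfg$genes_per_chrom) {
    stop("sim_config: n_translocations * translocation_block_genes exceeds the total gene count")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a reference genome and a derived, scaffolded genome
#'
#' Builds a reference genome of `n_chrom_ref` chromosomes with evenly
#' spaced gene models, then derives a second genome by applying, in
#' order: reciprocal block translocations, chromosome fissions, gene
#' losses, pseudogenizations, and fragmentation into scaffolds whose
#' gene counts are geometric with mean `scaffold_mean_genes`
#' (breakpoints only in intergenic space, so gene models stay intact).
#' A hit table links each surviving derived gene to its source locus on
#' the reference (bitscore 500 +/- 5) unless suppressed at
#' `hit_miss_rate`, plus spurious (bitscore in 50..300) and
#' equal-bitscore tie hits at the configured rates.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_dataset`: a list with elements
#'   `ref_annotation`, `derived_annotation` (gene data.frames as from
#'   [read_gff3_genes()]), `hits` (as from [read_blast_tab()]),
#'   `ref_lengths`, `derived_lengths`, `truth` and `config`.  `truth`
#'   holds `gene_origin` (derived gene -> source reference gene and
#'   origin chromosome), `scaffold_to_chrom` (majority origin per
#'   scaffold), `scaffold_order` (true scaffold order per derived
#'   chromosome), `lost_gene_ids`, `pseudogene_ids` and `event_log`.
#' @export
simulate_genomes <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  with_seed(config$seed, simulate_genomes_impl(config))
}

simulate_genomes_impl <- function(cfg) {
  spacing <- cfg$gene_len_bp + cfg$intergenic_bp
  n_genes <- cfg$n_chrom_ref * cfg$genes_per_chrom
  chrom_names <- paste0("chr", seq_len(cfg$n_chrom_ref))

  ref <- data.frame(
    gene_id = sprintf("ipu_g%05d", seq_len(n_genes)),
    seq_id = rep(chrom_names, each = cfg$genes_per_chrom),
    start = rep(cfg$intergenic_bp + (seq_len(cfg$genes_per_chrom) - 1L) * spacing,
                cfg$n_chrom_ref),
    end = NA_integer_, strand = "+", biotype = "protein_coding",
    stringsAsFactors = FALSE
  )
  ref$end <- ref$start + cfg$gene_len_bp
  ref_len_bp <- cfg$genes_per_chrom * spacing + cfg$intergenic_bp
  ref_lengths <- data.frame(seq_id = chrom_names, length_bp = ref_len_bp,
                            stringsAsFactors = FALSE)

  # Derived genome state: ordered gene indices per proto-chromosome.
  proto <- split(seq_len(n_genes),
                 factor(ref$seq_id, levels = chrom_names))
  proto_labels <- chrom_names
  event_log <- list()

  blk <- cfg$translocation_block_genes
  for (i in seq_len(cfg$n_translocations)) {
    eligible <- which(lengths(proto) >= blk)
    if (length(eligible) < 2L) {
      stop("simulate_genomes: no two chromosomes large enough for a translocation block")
    }
    pair <- resample(eligible, 2L)
    a <- pair[1L]; b <- pair[2L]
    ia <- sample.int(length(proto[[a]]) - blk + 1L, 1L)
    ib <- sample.int(length(proto[[b]]) - blk + 1L, 1L)
    ra <- ia:(ia + blk - 1L); rb <- ib:(ib + blk - 1L)
    block_a <- proto[[a]][ra]; block_b <- proto[[b]][rb]
    proto[[a]][ra] <- block_b
    proto[[b]][rb] <- block_a
    event_log[[length(event_log) + 1L]] <- list(
      type = "translocation", chrom_a = proto_labels[a],
      chrom_b = proto_labels[b], pos_a = ia, pos_b = ib,
      genes_a = ref$gene_id[block_a], genes_b = ref$gene_id[block_b]
    )
  }

  for (i in seq_len(cfg$n_fissions)) {
    eligible <- which(lengths(proto) >= 2L)
    if (length(eligible) == 0L) stop("simulate_genomes: no chromosome left to split")
    k <- resample(eligible, 1L)
    cut <- sample.int(length(proto[[k]]) - 1L, 1L)
    left <- proto[[k]][seq_len(cut)]
    right <- proto[[k]][(cut + 1L):length(proto[[k]])]
    lab <- proto_labels[k]
    proto <- append(proto[-k], list(left, right), after = k - 1L)
    proto_labels <- append(proto_labels[-k],
                           paste0(lab, c("_f1", "_f2")), after = k - 1L)
    event_log[[length(event_log) + 1L]] <- list(
      type = "fission", chrom = lab, after_gene = ref$gene_id[left[cut]]
    )
  }

  lost_gene_ids <- character(0)
  if (cfg$n_losses > 0L) {
    pool <- unlist(proto, use.names = FALSE)
    lose <- resample(pool, cfg$n_losses)
    proto <- lapply(proto, function(g) g[!g %in% lose])
    lost_gene_ids <- sort(ref$gene_id[lose])
    event_log[[length(event_log) + 1L]] <- list(
      type = "loss", genes = ref$gene_id[lose]
    )
  }

  pseudogene_ids <- character(0)
  if (cfg$n_pseudogenes > 0L) {
    pool <- unlist(proto, use.names = FALSE)
    ps <- resample(pool, min(cfg$n_pseudogenes, length(pool)))
    pseudogene_ids <- sort(ref$gene_id[ps])
    event_log[[length(event_log) + 1L]] <- list(
      type = "pseudogenization", genes = ref$gene_id[ps]
    )
  }

  # Fragmentation: scaffold gene counts ~ 1 + Geometric(1/mean).
  p_geo <- 1 / cfg$scaffold_mean_genes
  scaffold_genes <- list()
  scaffold_proto <- character(0)
  for (k in seq_along(proto)) {
    g <- proto[[k]]
    while (length(g) > 0L) {
      take <- if (p_geo >= 1) 1L else 1L + stats::rgeom(1L, p_geo)
      take <- min(take, length(g))
      scaffold_genes[[length(scaffold_genes) + 1L]] <- g[seq_len(take)]
      scaffold_proto <- c(scaffold_proto, proto_labels[k])
      g <- g[-seq_len(take)]
    }
  }
  n_scaf <- length(scaffold_genes)
  scaffold_ids <- sprintf("sc%07d", seq_len(n_scaf))
  event_log[[length(event_log) + 1L]] <- list(
    type = "fragmentation",
    scaffolds_per_chrom = as.list(table(factor(scaffold_proto,
                                               levels = unique(proto_labels))))
  )

  genes_per_scaf <- lengths(scaffold_genes)
  derived_ref_idx <- unlist(scaffold_genes, use.names = FALSE)
  n_d <- length(derived_ref_idx)
  d_scaffold <- rep(scaffold_ids, genes_per_scaf)
  d_pos <- sequence(genes_per_scaf)
  derived <- data.frame(
    gene_id = sprintf("phy_g%05d", seq_len(n_d)),
    seq_id = d_scaffold,
    start = cfg$intergenic_bp + (d_pos - 1L) * spacing,
    end = NA_integer_, strand = "+",
    biotype = ifelse(ref$gene_id[derived_ref_idx] %in% pseudogene_ids,
                     "pseudogene", "protein_coding"),
    stringsAsFactors = FALSE
  )
  derived$end <- derived$start + cfg$gene_len_bp
  derived_lengths <- data.frame(
    seq_id = scaffold_ids,
    length_bp = genes_per_scaf * spacing + cfg$intergenic_bp,
    stringsAsFactors = FALSE
  )

  gene_origin <- data.frame(
    derived_gene_id = derived$gene_id,
    ref_gene_id = ref$gene_id[derived_ref_idx],
    origin_chrom = ref$seq_id[derived_ref_idx],
    scaffold_id = d_scaffold, scaffold_pos = d_pos,
    stringsAsFactors = FALSE
  )
  majority <- vapply(split(gene_origin$origin_chrom, gene_origin$scaffold_id),
                     function(x) {
                       tab <- table(x)
                       sort(names(tab)[tab == max(tab)])[1L]
                     }, character(1))
  scaffold_to_chrom <- majority[scaffold_ids]
  scaffold_order <- split(scaffold_ids, factor(scaffold_proto,
                                               levels = unique(proto_labels)))

  # Hit table: one true hit per surviving gene (unless missed), plus noise.
  miss <- stats::runif(n_d) < cfg$hit_miss_rate
  true_bits <- round(500 + stats::runif(n_d, -5, 5), 1)
  true_pid <- round(stats::runif(n_d, 97.5, 99.9), 1)
  src <- derived_ref_idx
  true_hits <- data.frame(
    query_id = derived$gene_id, subject_id = ref$seq_id[src],
    pct_identity = true_pid, aln_len = cfg$gene_len_bp,
    mismatches = as.integer(round(cfg$gene_len_bp * (1 - true_pid / 100))),
    gap_opens = 0L, q_start = 1L, q_end = cfg$gene_len_bp,
    s_start = ref$start[src] + 1L, s_end = ref$end[src],
    evalue = 0, bitscore = true_bits, stringsAsFactors = FALSE
  )

  spur_sel <- which(stats::runif(n_d) < cfg$spurious_hit_rate)
  spur <- true_hits[spur_sel, , drop = FALSE]
  if (nrow(spur)) {
    spur$subject_id <- chrom_names[sample.int(cfg$n_chrom_ref, nrow(spur),
                                              replace = TRUE)]
    spur$aln_len <- 500L
    spur$q_start <- 1L; spur$q_end <- 500L
    spur$s_start <- sample.int(ref_len_bp - 500L, nrow(spur), replace = TRUE)
    spur$s_end <- spur$s_start + 499L
    spur$pct_identity <- round(stats::runif(nrow(spur), 80, 92), 1)
    spur$mismatches <- as.integer(round(500 * (1 - spur$pct_identity / 100)))
    spur$evalue <- signif(10^stats::runif(nrow(spur), -40, -10), 3)
    spur$bitscore <- round(stats::runif(nrow(spur), 50, 300), 1)
  }

  tie_sel <- which(stats::runif(n_d) < cfg$paralog_tie_rate & !miss)
  ties <- true_hits[tie_sel, , drop = FALSE]
  if (nrow(ties)) {
    # equal-bitscore second hit on a different chromosome
    other <- vapply(ties$subject_id, function(ch) {
      resample(setdiff(chrom_names, ch), 1L)
    }, character(1))
    ties$subject_id <- unname(other)
    ties$s_start <- sample.int(ref_len_bp - cfg$gene_len_bp, nrow(ties),
                               replace = TRUE)
    ties$s_end <- ties$s_start + cfg$gene_len_bp - 1L
  }

  hits <- rbind(true_hits[!miss, , drop = FALSE], spur, ties)
  hits <- hits[order(hits$query_id, -hits$bitscore, hits$subject_id,
                     method = "radix"), , drop = FALSE]
  rownames(hits) <- NULL

  structure(list(
    ref_annotation = ref, derived_annotation = derived, hits = hits,
    ref_lengths = ref_lengths, derived_lengths = derived_lengths,
    truth = list(
      gene_origin = gene_origin,
      scaffold_to_chrom = scaffold_to_chrom,
      scaffold_order = scaffold_order,
      lost_gene_ids = lost_gene_ids,
      pseudogene_ids = pseudogene_ids,
      event_log = event_log
    ),
    config = cfg
  ), class = "sim_dataset")
}

#' Plant syntenic gene losses into a simulated dataset
#'
#' Deletes the given reference genes from the derived annotation and hit
#' table while leaving their flanking genes untouched, reproducing the
#' configuration in which a gene (or adjacent gene cluster, like the
#' EEVS/MT-Ox sunscreen-biosynthesis pair) is absent from the query
#' genome but its conserved neighbours remain adjacent.
#'
#' @param dataset A `sim_dataset` from [simulate_genomes()].
#' @param target_gene_ids Reference gene IDs to delete.  Each must be
#'   present in the derived genome and interior (a neighbour on both
#'   sides, on its reference chromosome and on its derived scaffold).
#' @return The modified `sim_dataset`; `truth$lost_gene_ids` is extended
#'   and an event is appended to `truth$event_log`.
#' @export
plant_syntenic_loss <- function(dataset, target_gene_ids) {
  stopifnot(inherits(dataset, "sim_dataset"))
  go <- dataset$truth$gene_origin
  ref <- dataset$ref_annotation

  for (gid in target_gene_ids) {
    if (!gid %in% ref$gene_id) {
      stop(sprintf("plant_syntenic_loss: '%s' is not a reference gene", gid))
    }
    row <- which(go$ref_gene_id == gid)
    if (length(row) != 1L) {
      stop(sprintf("plant_syntenic_loss: '%s' is not present in the derived genome", gid))
    }
    # interior on the reference chromosome
    chrom_genes <- ref$gene_id[ref$seq_id == ref$seq_id[ref$gene_id == gid]]
    pos <- match(gid, chrom_genes)
    if (pos == 1L || pos == length(chrom_genes)) {
      stop(sprintf("no flank: '%s' sits at a reference chromosome edge", gid))
    }
    # interior on its derived scaffold
    scaf <- go$scaffold_id[row]
    n_on_scaf <- sum(go$scaffold_id == scaf)
    if (go$scaffold_pos[row] == 1L || go$scaffold_pos[row] == n_on_scaf) {
      stop(sprintf("no flank: '%s' sits at a scaffold edge", gid))
    }
  }

  rows <- match(target_gene_ids, go$ref_gene_id)
  derived_ids <- go$derived_gene_id[rows]
  dataset$derived_annotation <-
    dataset$derived_annotation[!dataset$derived_annotation$gene_id %in% derived_ids, ,
                               drop = FALSE]
  dataset$hits <- dataset$hits[!dataset$hits$query_id %in% derived_ids, ,
                               drop = FALSE]
  rownames(dataset$derived_annotation) <- NULL
  rownames(dataset$hits) <- NULL
  go <- go[-rows, , drop = FALSE]
  go$scaffold_pos <- stats::ave(go$scaffold_pos, go$scaffold_id,
                                FUN = seq_along)
  rownames(go) <- NULL
  dataset$truth$gene_origin <- go
  dataset$truth$lost_gene_ids <- sort(union(dataset$truth$lost_gene_ids,
                                            target_gene_ids))
  dataset$truth$event_log[[length(dataset$truth$event_log) + 1L]] <- list(
    type = "planted_syntenic_loss", genes = target_gene_ids
  )
  dataset
}

#' Pick interior reference genes suitable for planting losses
#'
#' Deterministically selects `n` evenly spaced reference genes that are
#' interior both on their reference chromosome and on their derived
#' scaffold, so they satisfy the preconditions of
#' [plant_syntenic_loss()].
#'
#' @param dataset A `sim_dataset`.
#' @param n Number of genes to pick.
#' @return Character vector of reference gene IDs.
#' @export
pick_interior_genes <- function(dataset, n) {
  go <- dataset$truth$gene_origin
  ref <- dataset$ref_annotation
  ref_pos <- stats::ave(seq_along(ref$gene_id), ref$seq_id, FUN = seq_along)
  ref_n <- stats::ave(seq_along(ref$gene_id), ref$seq_id, FUN = length)
  interior_ref <- ref$gene_id[ref_pos > 1L & ref_pos < ref_n]
  scaf_n <- stats::ave(go$scaffold_pos, go$scaffold_id, FUN = length)
  interior_scaf <- go$ref_gene_id[go$scaffold_pos > 1L & go$scaffold_pos < scaf_n]
  cand <- sort(intersect(interior_ref, interior_scaf))
  if (length(cand) < n) stop("pick_interior_genes: not enough interior genes")
  # evenly spaced, then thinned so no two picks are reference-adjacent
  picks <- cand[unique(as.integer(round(seq(1, length(cand), length.out = n))))]
  if (length(picks) < n) picks <- cand[seq_len(n)]
  picks
}

#' Write a simulated dataset to disk
#'
#' Emits `ref.gff3`, `derived.gff3`, `hits.tsv` (12-column tabular BLAST
#' dialect), `ref.lengths.tsv`, `derived.lengths.tsv` and `truth.json`.
#'
#' @param dataset A `sim_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gff3_genes(dataset$ref_annotation, file.path(dir, "ref.gff3"))
  write_gff3_genes(dataset$derived_annotation, file.path(dir, "derived.gff3"))
  write_blast_tab(dataset$hits, file.path(dir, "hits.tsv"))
  write_lengths(dataset$ref_lengths, file.path(dir, "ref.lengths.tsv"))
  write_lengths(dataset$derived_lengths, file.path(dir, "derived.lengths.tsv"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
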