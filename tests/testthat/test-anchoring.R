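# Majority-vote anchoring, the strict >50% rule, and the bp summary.

# scaffold with a prescribed vote profile: genes g1..gN on one scaffold,
# each hitting its designated chromosome once
vote_fixture <- function(chroms, scaffold = "sc1", len = 2e6) {
  ids <- sprintf("g%02d", seq_along(chroms))
  ann <- make_genes(ids, scaffold, starts = seq_along(chroms) * 1000L)
  hits <- make_hits(query = ids, subject = chroms, bitscore = 500)
  lengths <- data.frame(seq_id = scaffold, length_bp = len)
  list(assignments = best_hits(hits), annotation = ann, lengths = lengths)
}

test_that("better than 50% of gene matches on one chromosome means conserved", {
  fx <- vote_fixture(c(rep("chr5", 6), rep("chr2", 4)))
  call <- anchor_scaffolds(fx$assignments, fx$annotation, fx$lengths,
                           min_len_bp = 0)
  expect_equal(call$assigned_chrom, "chr5")
  expect_equal(call$top_fraction, 0.6)
  expect_equal(call$klass, "conserved")
  expect_false(call$ambiguous)
})

test_that("exactly 50% is rearranged: the rule is strictly better-than-50%", {
  fx <- vote_fixture(c(rep("chr1", 5), rep("chr2", 5)))
  call <- anchor_scaffolds(fx$assignments, fx$annotation, fx$lengths,
                           min_len_bp = 0)
  expect_equal(call$assigned_chrom, "chr1")  # lexicographic tie-break
  expect_equal(call$top_fraction, 0.5)
  expect_equal(call$klass, "rearranged")
  expect_true(call$ambiguous)
})

test_that("a scaffold with genes but no assignments is unplaced", {
  ann <- make_genes(c("g1", "g2"), "sc1", c(1000L, 5000L))
  lengths <- data.frame(seq_id = "sc1", length_bp = 2e6)
  call <- anchor_scaffolds(best_hits(make_hits(character(0), character(0),
                                               numeric(0))),
                           ann, lengths, min_len_bp = 0)
  expect_equal(call$klass, "unplaced")
  expect_true(is.na(call$assigned_chrom))
})

test_that("scaffolds below min_len_bp are excluded but reported", {
  ann <- rbind(make_genes("g1", "big", 1000L), make_genes("g2", "small", 1000L))
  hits <- make_hits(query = c("g1", "g2"), subject = "chr1", bitscore = 500)
  lengths <- data.frame(seq_id = c("big", "small"), length_bp = c(2e6, 5e5))
  calls <- anchor_scaffolds(best_hits(hits), ann, lengths, min_len_bp = 1e6)
  expect_equal(calls$scaffold_id, "big")
  expect_equal(attr(calls, "excluded")$scaffold_id, "small")
})

test_that("a scaffold missing from the length table is a validation error", {
  ann <- make_genes("g1", "sc1", 1000L)
  lengths <- data.frame(seq_id = "other", length_bp = 1e6)
  expect_error(anchor_scaffolds(best_hits(make_hits("g1", "chr1", 500)),
                                ann, lengths),
               "missing from lengths")
})

test_that("anchoring matches an independent brute-force recount on simulations", {
  d <- simulate_genomes(sim_config(seed = 11, n_chrom_ref = 8,
                                   genes_per_chrom = 60,
                                   n_translocations = 4,
                                   scaffold_mean_genes = 6,
                                   hit_miss_rate = 0.1,
                                   spurious_hit_rate = 0.05,
                                   paralog_tie_rate = 0.05))
  calls <- anchor_scaffolds(best_hits(d$hits), d$derived_annotation,
                            d$derived_lengths, min_len_bp = 0)
  oracle <- oracle_anchor_klass(d$hits, d$derived_annotation,
                                d$derived_lengths)
  expect_equal(calls$scaffold_id, oracle$scaffold_id)
  expect_equal(calls$klass, oracle$klass)
  expect_equal(calls$assigned_chrom, oracle$assigned_chrom)
  # partition: every eligible scaffold is in exactly one class
  expect_true(all(calls$klass %in% c("conserved", "rearranged", "unplaced")))
  expect_setequal(calls$scaffold_id, unique(d$derived_annotation$seq_id))
  # votes sum to n_hit_genes <= n_genes
  expect_equal(vapply(calls$votes, sum, numeric(1)), as.numeric(calls$n_hit_genes))
  expect_true(all(calls$n_hit_genes <= calls$n_genes))
})

test_that("anchoring is invariant to hit-table row order", {
  d <- simulate_genomes(sim_config(seed = 4, n_chrom_ref = 4,
                                   genes_per_chrom = 40,
                                   n_translocations = 2))
  set.seed(2)
  hp <- d$hits[sample.int(nrow(d$hits)), , drop = FALSE]
  rownames(hp) <- NULL
  c1 <- anchor_scaffolds(best_hits(d$hits), d$derived_annotation,
                         d$derived_lengths, min_len_bp = 0)
  c2 <- anchor_scaffolds(best_hits(hp), d$derived_annotation,
                         d$derived_lengths, min_len_bp = 0)
  expect_equal(c1, c2)
})

test_that("summary reproduces the two-class percentage arithmetic", {
  calls <- data.frame(
    scaffold_id = c("a", "b"),
    scaffold_len = c(417e6, 298e6),
    klass = c("conserved", "rearranged"),
    stringsAsFactors = FALSE
  )
  s <- anchor_summary(calls)
  expect_equal(unname(s$share_pct), c(58L, 42L))
  expect_equal(s$total_bp, 715e6)

  # single conserved scaffold: 100%
  s1 <- anchor_summary(calls[1, , drop = FALSE])
  expect_equal(s1$share_pct[["conserved"]], 100L)

  expect_error(anchor_summary(calls[0, , drop = FALSE]), "nothing to summarize")
})

test_that("integer shares always sum to exactly 100 (largest remainder)", {
  set.seed(2)
  for (i in 1:1000) {
    bp <- stats::runif(2, 1, 1e9)
    calls <- data.frame(
      scaffold_id = c("a", "b"), scaffold_len = bp,
      klass = c("conserved", "rearranged"), stringsAsFactors = FALSE
    )
    s <- anchor_summary(calls)
    if (sum(s$share_pct) != 100L) {
      fail(sprintf("shares sum to %d for bp = (%f, %f)",
                   sum(s$share_pct), bp[1], bp[2]))
    }
  }
  succeed()
})
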