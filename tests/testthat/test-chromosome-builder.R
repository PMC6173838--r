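# Ordering/orienting anchored scaffolds and the AGP emitter.

builder_fixture <- function(gene_tbl, scaffold_lens) {
  # gene_tbl: data.frame(gene, scaffold, start, chrom, mid)
  ann <- make_genes(gene_tbl$gene, gene_tbl$scaffold, gene_tbl$start)
  hits <- make_hits(query = gene_tbl$gene, subject = gene_tbl$chrom,
                    bitscore = 500,
                    s_start = gene_tbl$mid, s_end = gene_tbl$mid + 99L)
  lengths <- data.frame(seq_id = names(scaffold_lens),
                        length_bp = unname(scaffold_lens))
  a <- best_hits(hits)
  calls <- anchor_scaffolds(a, ann, lengths, min_len_bp = 0)
  list(ann = ann, a = a, calls = calls, lengths = lengths)
}

test_that("a single-gene scaffold is placed forward with low confidence", {
  fx <- builder_fixture(
    data.frame(gene = "g1", scaffold = "sc1", start = 1000L,
               chrom = "chr1", mid = 50000L),
    c(sc1 = 1e6)
  )
  pl <- place_scaffolds(fx$calls, fx$a, fx$ann)
  expect_equal(pl$order_index, 0L)
  expect_equal(pl$orientation, "+")
  expect_true(pl$low_confidence)
  expect_equal(pl$orientation_support, 0L)
})

test_that("scaffolds are ordered by median subject position", {
  fx <- builder_fixture(
    data.frame(gene = c("a1", "a2", "b1", "b2"),
               scaffold = c("scB", "scB", "scA", "scA"),
               start = c(1000L, 9000L, 1000L, 9000L),
               chrom = "chr1",
               mid = c(5000000L, 5010000L, 1000000L, 1010000L)),
    c(scA = 1e6, scB = 1e6)
  )
  pl <- place_scaffolds(fx$calls, fx$a, fx$ann)
  pl <- pl[order(pl$order_index), ]
  # scA median 1.0 Mb precedes scB median 5.0 Mb
  expect_equal(pl$scaffold_id, c("scA", "scB"))
  expect_equal(pl$order_index, c(0L, 1L))
  expect_equal(pl$orientation, c("+", "+"))
})

test_that("genes running against the reference order give orientation -", {
  # scaffold order left-to-right, subject positions high-to-low
  fx <- builder_fixture(
    data.frame(gene = c("g1", "g2", "g3"), scaffold = "sc1",
               start = c(1000L, 11000L, 21000L),
               chrom = "chr2", mid = c(300000L, 200000L, 100000L)),
    c(sc1 = 1e6)
  )
  pl <- place_scaffolds(fx$calls, fx$a, fx$ann)
  # brute-force sign: all 3 informative pairs are discordant
  expect_equal(pl$orientation, "-")
  expect_equal(pl$orientation_support, 3L)
  expect_false(pl$low_confidence)
})

test_that("AGP arithmetic: components and gaps tile the object", {
  pl <- data.frame(
    scaffold_id = c("sc1", "sc2"), target_chrom = "chr1",
    order_index = 0:1, orientation = c("+", "-"),
    median_subject_pos = c(1, 2), orientation_support = 1L,
    low_confidence = FALSE, scaffold_len = c(1000, 500),
    stringsAsFactors = FALSE
  )
  lengths <- data.frame(seq_id = c("sc1", "sc2"), length_bp = c(1000, 500))
  agp <- emit_agp(pl, lengths, gap_len = 100)
  expect_equal(agp$part_number, 1:3)
  expect_equal(max(agp$object_end), 1600L)
  expect_equal(agp$component_type, c("W", "U", "W"))
  expect_equal(agp$object_id, rep("hypChr1", 3))

  # single scaffold: one W row, no gap
  agp1 <- emit_agp(pl[1, ], lengths, gap_len = 100)
  expect_equal(nrow(agp1), 1L)
  expect_equal(agp1$component_type, "W")

  # duplicate order_index is rejected
  bad <- pl; bad$order_index <- c(0L, 0L)
  expect_error(emit_agp(bad, lengths), "duplicate order_index")
})

test_that("emitted AGP read back reconstructs order and orientation", {
  d <- simulate_genomes(zero_noise_config(seed = 6, n_chrom_ref = 3,
                                          genes_per_chrom = 50,
                                          scaffold_mean_genes = 8,
                                          n_fissions = 0))
  a <- best_hits(d$hits)
  calls <- anchor_scaffolds(a, d$derived_annotation, d$derived_lengths,
                            min_len_bp = 0)
  pl <- place_scaffolds(calls, a, d$derived_annotation)
  f <- withr::local_tempfile(fileext = ".agp")
  write_agp(emit_agp(pl, d$derived_lengths), f)
  back <- read_agp(f)
  w <- back[back$component_type == "W", ]
  for (obj in unique(w$object_id)) {
    chrom <- paste0("chr", sub("^hypChr", "", obj))
    expect_equal(w$component_id[w$object_id == obj],
                 pl$scaffold_id[pl$target_chrom == chrom][
                   order(pl$order_index[pl$target_chrom == chrom]) ],
                 label = obj)
  }
  expect_equal(w$orientation,
               pl$orientation[match(w$component_id, pl$scaffold_id)])
  # object length = sum of scaffold lengths + (n-1) gaps per chromosome
  for (obj in unique(back$object_id)) {
    r <- back[back$object_id == obj, ]
    n_w <- sum(r$component_type == "W")
    lens <- d$derived_lengths$length_bp[match(
      r$component_id[r$component_type == "W"], d$derived_lengths$seq_id)]
    expect_equal(max(r$object_end), sum(lens) + (n_w - 1) * 100)
  }
})

test_that("noise-free fragmentation order is recovered on every chromosome", {
  d <- simulate_genomes(zero_noise_config(seed = 17, n_chrom_ref = 5,
                                          genes_per_chrom = 60,
                                          scaffold_mean_genes = 7,
                                          n_fissions = 0))
  a <- best_hits(d$hits)
  calls <- anchor_scaffolds(a, d$derived_annotation, d$derived_lengths,
                            min_len_bp = 0)
  pl <- place_scaffolds(calls, a, d$derived_annotation)
  for (chrom in names(d$truth$scaffold_order)) {
    sel <- pl[pl$target_chrom == chrom, ]
    got <- sel$scaffold_id[order(sel$order_index)]
    expect_equal(got, d$truth$scaffold_order[[chrom]], label = chrom)
  }
  expect_true(all(pl$orientation == "+"))
})

test_that("a call referencing an unknown scaffold is a validation error", {
  fx <- builder_fixture(
    data.frame(gene = "g1", scaffold = "sc1", start = 1000L,
               chrom = "chr1", mid = 1000L),
    c(sc1 = 1e6)
  )
  bad <- fx$calls
  bad$scaffold_id <- "ghost"
  expect_error(place_scaffolds(bad, fx$a, fx$ann), "unknown scaffold")
})
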