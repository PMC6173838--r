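# External-format readers and writers.
#
# Internal coordinate contract: every gene interval inside the package is
# 0-based half-open [start, end), so length = end - start.  GFF3 and AGP are
# 1-based inclusive on disk; conversion happens only here, at the boundary.

BLAST_TAB_COLS <- c(
  "query_id", "subject_id", "pct_identity", "aln_len", "mismatches",
  "gap_opens", "q_start", "q_end", "s_start", "s_end", "evalue", "bitscore"
)

AGP_COLS <- c(
  "object_id", "object_start", "object_end", "part_number", "component_type",
  "component_id", "component_start", "component_end", "orientation",
  "gap_length", "gap_type", "linkage", "evidence"
)

#' Read gene records from a GFF3 file
#'
#' Consumes only rows of type `gene` or `pseudogene`; mRNA/exon/CDS rows and
#' feature hierarchies are ignored.  External 1-based inclusive coordinates
#' are converted to the internal 0-based half-open convention, and records
#' are returned sorted by `(seq_id, start)`.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `gene_id`, `seq_id`, `start`, `end`
#'   (0-based half-open), `strand` (`+`/`-`) and `biotype`
#'   (`protein_coding` or `pseudogene`).
#' @examples
#' f <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "s1\tsrc\tgene\t1\t100\t.\t+\t.\tID=g1"), f)
#' read_gff3_genes(f)
#' @export
read_gff3_genes <- function(path) {
  lines <- readLines(path)
  idx <- which(!grepl("^#", lines) & nzchar(lines))
  empty <- data.frame(
    gene_id = character(), seq_id = character(), start = integer(),
    end = integer(), strand = character(), biotype = character(),
    stringsAsFactors = FALSE
  )
  if (length(idx) == 0L) return(empty)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1L]
    stop(sprintf("malformed GFF3 row at line %d: expected 9 columns, found %d",
                 idx[bad], nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  keep <- m[, 3L] %in% c("gene", "pseudogene")
  if (!any(keep)) return(empty)
  m <- m[keep, , drop = FALSE]
  lns <- idx[keep]

  start1 <- suppressWarnings(as.integer(m[, 4L]))
  end1 <- suppressWarnings(as.integer(m[, 5L]))
  bad <- which(is.na(start1) | is.na(end1))
  if (length(bad)) {
    stop(sprintf("non-numeric coordinate in GFF3 at line %d", lns[bad[1L]]))
  }
  if (any(start1 < 1L | end1 < start1)) {
    bad <- which(start1 < 1L | end1 < start1)[1L]
    stop(sprintf("invalid GFF3 coordinates at line %d: start=%d end=%d",
                 lns[bad], start1[bad], end1[bad]))
  }
  strand <- m[, 7L]
  if (any(!strand %in% c("+", "-"))) {
    bad <- which(!strand %in% c("+", "-"))[1L]
    stop(sprintf("invalid strand %s in GFF3 at line %d", strand[bad], lns[bad]))
  }

  attr_id <- regmatches(m[, 9L], regexpr("(?:^|;)ID=[^;]+", m[, 9L], perl = TRUE))
  has_id <- grepl("(?:^|;)ID=[^;]+", m[, 9L], perl = TRUE)
  if (!all(has_id)) {
    stop(sprintf("GFF3 gene row without ID attribute at line %d",
                 lns[which(!has_id)[1L]]))
  }
  ids <- sub("^;?ID=", "", attr_id)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop(sprintf("duplicate gene ID '%s' in %s", dup, path))
  }

  out <- data.frame(
    gene_id = ids, seq_id = m[, 1L],
    start = start1 - 1L, end = end1,
    strand = strand,
    biotype = ifelse(m[, 3L] == "pseudogene", "pseudogene", "protein_coding"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$seq_id, out$start, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write gene records to a GFF3 file
#'
#' Inverse of [read_gff3_genes()]: internal 0-based half-open coordinates are
#' converted back to 1-based inclusive, and biotype `pseudogene` is written
#' as a `pseudogene`-type row.
#'
#' @param genes A gene data.frame as returned by [read_gff3_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path) {
  stopifnot(all(c("gene_id", "seq_id", "start", "end", "strand", "biotype")
                %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) {
    stop(sprintf("duplicate gene ID '%s'",
                 genes$gene_id[duplicated(genes$gene_id)][1L]))
  }
  type <- ifelse(genes$biotype == "pseudogene", "pseudogene", "gene")
  rows <- paste(genes$seq_id, "syntanchor", type,
                genes$start + 1L, genes$end, ".", genes$strand, ".",
                paste0("ID=", genes$gene_id), sep = "\t")
  writeLines(c("##gff-version 3", rows), path)
  invisible(path)
}

#' Read a 12-column tabular BLAST hit file (outfmt 6)
#'
#' @param path Path to a tab-separated hit table with the 12 standard
#'   columns (qseqid sseqid pident length mismatch gapopen qstart qend
#'   sstart send evalue bitscore).  Row order is preserved.
#' @return A data.frame with columns `query_id`, `subject_id`,
#'   `pct_identity`, `aln_len`, `mismatches`, `gap_opens`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `evalue`, `bitscore`.  Subject
#'   coordinates stay 1-based inclusive as in the source dialect.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  empty <- stats::setNames(
    data.frame(character(), character(), numeric(), integer(), integer(),
               integer(), integer(), integer(), integer(), integer(),
               numeric(), numeric(), stringsAsFactors = FALSE),
    BLAST_TAB_COLS
  )
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1L]
    stop(sprintf("malformed hit table at line %d: expected 12 columns, found %d",
                 bad, nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num <- function(col, what, as_int = FALSE) {
    x <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(x)) {
      stop(sprintf("non-numeric %s at line %d", what, which(is.na(x))[1L]))
    }
    if (as_int) as.integer(x) else x
  }
  out <- data.frame(
    query_id = m[, 1L], subject_id = m[, 2L],
    pct_identity = num(3L, "pct_identity"),
    aln_len = num(4L, "aln_len", TRUE),
    mismatches = num(5L, "mismatches", TRUE),
    gap_opens = num(6L, "gap_opens", TRUE),
    q_start = num(7L, "q_start", TRUE), q_end = num(8L, "q_end", TRUE),
    s_start = num(9L, "s_start", TRUE), s_end = num(10L, "s_end", TRUE),
    evalue = num(11L, "evalue"), bitscore = num(12L, "bitscore"),
    stringsAsFactors = FALSE
  )
  if (any(out$aln_len < 1L) || any(out$bitscore < 0) ||
      any(out$pct_identity < 0 | out$pct_identity > 100)) {
    stop("hit table violates invariants (aln_len >= 1, bitscore >= 0, 0 <= pct_identity <= 100)")
  }
  out
}

#' Write a hit table in the 12-column tabular BLAST dialect
#'
#' Numbers are written in canonical R form so that
#' `write_blast_tab(read_blast_tab(f))` reproduces a file this writer
#' produced byte-identically (modulo trailing newline).
#'
#' @param hits A data.frame as returned by [read_blast_tab()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  stopifnot(all(BLAST_TAB_COLS %in% names(hits)))
  h <- hits[BLAST_TAB_COLS]
  rows <- do.call(paste, c(lapply(h, as.character), sep = "\t"))
  writeLines(rows, path)
  invisible(path)
}

#' Read a scaffold/chromosome length table
#'
#' @param path Two-column headerless TSV: `seq_id<TAB>length_bp`.
#' @return data.frame with columns `seq_id`, `length_bp`.
#' @export
read_lengths <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = c("character", "numeric"))
  names(x) <- c("seq_id", "length_bp")
  if (anyNA(x$length_bp) || any(x$length_bp <= 0)) {
    stop("length table contains missing or non-positive lengths")
  }
  x
}

#' Write a scaffold/chromosome length table
#'
#' @param lengths data.frame with columns `seq_id`, `length_bp`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lengths <- function(lengths, path) {
  writeLines(paste(lengths$seq_id, format(lengths$length_bp, scientific = FALSE,
                                          trim = TRUE), sep = "\t"), path)
  invisible(path)
}

validate_agp <- function(rows) {
  stopifnot(all(AGP_COLS %in% names(rows)))
  if (!all(rows$component_type %in% c("W", "U"))) {
    stop("AGP component_type must be W or U")
  }
  for (obj in unique(rows$object_id)) {
    r <- rows[rows$object_id == obj, , drop = FALSE]
    r <- r[order(r$part_number), , drop = FALSE]
    if (!identical(as.integer(r$part_number), seq_len(nrow(r)))) {
      stop(sprintf("AGP object %s: part_numbers not consecutive from 1", obj))
    }
    expected_start <- c(1L, utils::head(r$object_end, -1L) + 1L)
    if (!identical(as.integer(r$object_start), as.integer(expected_start))) {
      stop(sprintf("AGP object %s: parts do not tile object coordinates contiguously", obj))
    }
    span <- r$object_end - r$object_start + 1L
    comp_span <- ifelse(r$component_type == "W",
                        r$component_end - r$component_start + 1L,
                        r$gap_length)
    if (any(span != comp_span)) {
      stop(sprintf("AGP object %s: object span does not match component span", obj))
    }
    w <- r$component_type == "W"
    if (any(!r$orientation[w] %in% c("+", "-"))) {
      stop(sprintf("AGP object %s: W rows need orientation + or -", obj))
    }
  }
  invisible(rows)
}

#' Read an AGP 2.1 file
#'
#' @param path Path to an AGP file; `#` comment lines are skipped.
#' @return A data.frame with one row per AGP part and columns
#'   `object_id`, `object_start`, `object_end`, `part_number`,
#'   `component_type` (`W` or `U`), the W-specific columns
#'   `component_id`, `component_start`, `component_end`, `orientation`,
#'   and the U-specific columns `gap_length`, `gap_type`, `linkage`,
#'   `evidence` (NA where not applicable).  Coordinates stay 1-based
#'   inclusive as in the format.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) stop("empty AGP file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 9L)) {
    bad <- which(lengths(fields) != 9L)[1L]
    stop(sprintf("malformed AGP row %d: expected 9 columns", bad))
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  is_w <- m[, 5L] == "W"
  rows <- data.frame(
    object_id = m[, 1L],
    object_start = as.integer(m[, 2L]),
    object_end = as.integer(m[, 3L]),
    part_number = as.integer(m[, 4L]),
    component_type = m[, 5L],
    component_id = ifelse(is_w, m[, 6L], NA_character_),
    component_start = ifelse(is_w, suppressWarnings(as.integer(m[, 7L])), NA_integer_),
    component_end = ifelse(is_w, suppressWarnings(as.integer(m[, 8L])), NA_integer_),
    orientation = ifelse(is_w, m[, 9L], NA_character_),
    gap_length = ifelse(is_w, NA_integer_, suppressWarnings(as.integer(m[, 6L]))),
    gap_type = ifelse(is_w, NA_character_, m[, 7L]),
    linkage = ifelse(is_w, NA_character_, m[, 8L]),
    evidence = ifelse(is_w, NA_character_, m[, 9L]),
    stringsAsFactors = FALSE
  )
  validate_agp(rows)
}

#' Write an AGP 2.1 file
#'
#' Validates the typed rows (contiguous tiling, consecutive part numbers)
#' before writing; `read_agp(write_agp(rows))` is the identity on the typed
#' content.
#'
#' @param rows An AGP data.frame as returned by [read_agp()] or
#'   [emit_agp()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agp <- function(rows, path) {
  validate_agp(rows)
  is_w <- rows$component_type == "W"
  c6 <- ifelse(is_w, rows$component_id, as.character(rows$gap_length))
  c7 <- ifelse(is_w, as.character(rows$component_start), rows$gap_type)
  c8 <- ifelse(is_w, as.character(rows$component_end), rows$linkage)
  c9 <- ifelse(is_w, rows$orientation, rows$evidence)
  out <- paste(rows$object_id, rows$object_start, rows$object_end,
               rows$part_number, rows$component_type, c6, c7, c8, c9,
               sep = "\t")
  writeLines(c("##agp-version 2.1", out), path)
  invisible(path)
}
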