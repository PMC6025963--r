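# Splice-junction table and annotation IO.
#
# All coordinates are 1-based inclusive intron endpoints (the STAR SJ.out.tab
# convention): intron_start is the first intronic base, intron_end the last.

.sj_motifs <- c("non-canonical", "GT/AG", "CT/AC", "GC/AG", "CT/GC",
                "AT/AC", "GT/AT")
.sj_strands <- c("*", "+", "-")

#' Junction identifier
#'
#' Canonical string key `chrom:intron_start-intron_end` used to index
#' count matrices and structure membership.
#'
#' @param junctions Data frame with columns `chrom`, `intron_start`,
#'   `intron_end`.
#' @return Character vector of junction ids.
#' @export
junction_id <- function(junctions) {
  sprintf("%s:%d-%d", junctions$chrom,
          as.integer(junctions$intron_start),
          as.integer(junctions$intron_end))
}

#' Read a splice-junction table (STAR `SJ.out.tab` dialect)
#'
#' Parses the 9-column whitespace-delimited junction table emitted by the
#' STAR aligner: chromosome, 1-based inclusive intron start and end, strand
#' code (0 undefined, 1 `+`, 2 `-`), splice-motif code (0-6), annotation
#' flag, uniquely-mapped read count, multi-mapped read count, and maximum
#' spliced-alignment overhang.
#'
#' @param path Path to an `SJ.out.tab` file.
#' @return A data frame with one row per junction and columns `chrom`,
#'   `intron_start`, `intron_end`, `strand` (`+`, `-`, `*`), `motif`
#'   (non-canonical, GT/AG, CT/AC, GC/AG, CT/GC, AT/AC or GT/AT),
#'   `annotated` (logical),
#'   `unique_reads`, `multi_reads`, `max_overhang`. Input order is preserved.
#' @export
read_sj_table <- function(path) {
  if (!file.exists(path)) stop("splice-junction table not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_sj_table())
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    i <- which(nf != 9L)[1L]
    stop(sprintf("parse error in %s, line %d: expected 9 fields, found %d",
                 path, lineno[i], nf[i]))
  }
  m <- matrix(unlist(fields, use.names = FALSE), ncol = 9L, byrow = TRUE)
  num <- suppressWarnings(matrix(as.integer(m[, 2:9]), ncol = 8L))
  if (anyNA(num)) {
    i <- which(rowSums(is.na(num)) > 0L)[1L]
    stop(sprintf("parse error in %s, line %d: non-integer numeric field",
                 path, lineno[i]))
  }
  if (any(num[, 3L] < 0L | num[, 3L] > 2L))
    stop("parse error in ", path, ": strand code outside 0..2")
  if (any(num[, 4L] < 0L | num[, 4L] > 6L))
    stop("parse error in ", path, ": motif code outside 0..6")
  if (any(num[, 1L] > num[, 2L]))
    stop("parse error in ", path, ": intron_start > intron_end")
  if (any(num[, 6:7] < 0L))
    stop("parse error in ", path, ": negative read count")
  data.frame(
    chrom = m[, 1L],
    intron_start = num[, 1L],
    intron_end = num[, 2L],
    strand = .sj_strands[num[, 3L] + 1L],
    motif = .sj_motifs[num[, 4L] + 1L],
    annotated = num[, 5L] != 0L,
    unique_reads = num[, 6L],
    multi_reads = num[, 7L],
    max_overhang = num[, 8L],
    stringsAsFactors = FALSE
  )
}

empty_sj_table <- function() {
  data.frame(chrom = character(), intron_start = integer(),
             intron_end = integer(), strand = character(),
             motif = character(), annotated = logical(),
             unique_reads = integer(), multi_reads = integer(),
             max_overhang = integer(), stringsAsFactors = FALSE)
}

#' Write a splice-junction table (STAR `SJ.out.tab` dialect)
#'
#' Inverse of [read_sj_table()]; `read_sj_table(write_sj_table(x, f))`
#' reproduces `x` field for field.
#'
#' @param junctions Junction data frame as returned by [read_sj_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sj_table <- function(junctions, path) {
  strand_code <- match(junctions$strand, .sj_strands) - 1L
  motif_code <- match(junctions$motif, .sj_motifs) - 1L
  if (anyNA(strand_code)) stop("invalid strand value")
  if (anyNA(motif_code)) stop("invalid motif value")
  out <- data.frame(junctions$chrom, junctions$intron_start,
                    junctions$intron_end, strand_code, motif_code,
                    as.integer(junctions$annotated), junctions$unique_reads,
                    junctions$multi_reads, junctions$max_overhang)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Filter junctions by read support
#'
#' Two support modes are available. `"all-samples"` keeps junctions whose
#' uniquely-mapped read count strictly exceeds `min_unique_reads` in every
#' sample (used for two pooled condition datasets in differential analysis).
#' `"per-replica-any-timepoint"` keeps junctions exceeding the threshold in
#' at least one timepoint within *each* replicate day (used for cycling
#' analysis); `replicas` assigns each sample column to its replicate day.
#' "More than `min_unique_reads`" is strict: with the default 10, a junction
#' needs >= 11 reads.
#'
#' @param counts Numeric matrix of unique read counts, junctions x samples
#'   (a vector is treated as a one-junction matrix).
#' @param min_unique_reads Support threshold (default 10, strict).
#' @param mode `"all-samples"` or `"per-replica-any-timepoint"`.
#' @param replicas Factor or vector over columns of `counts` naming the
#'   replicate day of each sample; required for mode
#'   `"per-replica-any-timepoint"`.
#' @return Logical vector over junctions (rows), `TRUE` for kept junctions.
#' @export
filter_by_support <- function(counts, min_unique_reads = 10,
                              mode = c("all-samples",
                                       "per-replica-any-timepoint"),
                              replicas = NULL) {
  mode <- match.arg(mode)
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  if (min_unique_reads < 0) stop("min_unique_reads must be >= 0")
  pass <- counts > min_unique_reads
  if (mode == "all-samples") {
    keep <- rowSums(pass) == ncol(counts)
  } else {
    if (is.null(replicas))
      stop("mode 'per-replica-any-timepoint' requires `replicas`")
    if (length(replicas) != ncol(counts))
      stop("`replicas` must have one entry per sample column")
    replicas <- factor(replicas)
    keep <- rep(TRUE, nrow(counts))
    for (lev in levels(replicas)) {
      cols <- which(replicas == lev)
      keep <- keep & (rowSums(pass[, cols, drop = FALSE]) > 0L)
    }
  }
  stats::setNames(keep, rownames(counts))
}

#' Assign junctions to containing genes
#'
#' A junction is assigned to a gene whose span fully contains the interval
#' `[intron_start - 1, intron_end + 1]` (the intron plus one flanking exonic
#' base on each side) on the same chromosome. Junctions contained by several
#' overlapping genes are flagged ambiguous and all containing gene ids are
#' reported.
#'
#' @param junctions Junction data frame (`chrom`, `intron_start`,
#'   `intron_end`).
#' @param gene_models Data frame with columns `gene_id`, `chrom`, `start`,
#'   `end` (1-based inclusive gene spans).
#' @return Data frame with one row per junction: `gene_id` (`NA` if
#'   intergenic; comma-joined when ambiguous), `n_genes`, and `ambiguous`.
#' @export
assign_to_gene <- function(junctions, gene_models) {
  if (nrow(junctions) == 0L) {
    return(data.frame(gene_id = character(), n_genes = integer(),
                      ambiguous = logical(), stringsAsFactors = FALSE))
  }
  q <- GenomicRanges::GRanges(
    junctions$chrom,
    IRanges::IRanges(junctions$intron_start - 1L, junctions$intron_end + 1L))
  s <- GenomicRanges::GRanges(
    gene_models$chrom,
    IRanges::IRanges(gene_models$start, gene_models$end))
  hits <- GenomicRanges::findOverlaps(q, s, type = "within")
  qh <- S4Vectors::queryHits(hits)
  gh <- gene_models$gene_id[S4Vectors::subjectHits(hits)]
  ids <- vapply(split(gh, factor(qh, levels = seq_len(nrow(junctions)))),
                function(g) if (length(g)) paste(sort(g), collapse = ",")
                            else NA_character_,
                character(1))
  n <- tabulate(qh, nbins = nrow(junctions))
  data.frame(gene_id = unname(ids), n_genes = n, ambiguous = n > 1L,
             stringsAsFactors = FALSE)
}

#' Read gene models and the annotated-junction library from a GTF file
#'
#' Gene spans come from `gene` features (or, if absent, from the range of
#' each gene's exons). Annotated splice junctions are derived from
#' consecutive exon pairs of every transcript: the intron between exons
#' ending at `e` and starting at `s` is `[e + 1, s - 1]`. Junctions shared
#' by several transcripts are recorded once.
#'
#' @param path Path to a GTF file (ensembl/FlyBase attribute dialect with
#'   `gene_id` and `transcript_id`).
#' @return A list with elements `genes` (data frame: `gene_id`, `chrom`,
#'   `start`, `end`, `strand`) and `junctions` (data frame: `chrom`,
#'   `intron_start`, `intron_end`, `strand`), plus `junction_ids`, the
#'   annotated-junction key set for exact-coordinate lookup.
#' @export
read_gtf_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  if (!"gene_id" %in% colnames(mc) || anyNA(mc$gene_id))
    stop("parse error: GTF records lack a gene_id attribute")
  type <- as.character(mc$type)
  genes_gr <- gr[type == "gene"]
  if (length(genes_gr)) {
    genes <- data.frame(
      gene_id = S4Vectors::mcols(genes_gr)$gene_id,
      chrom = as.character(GenomicRanges::seqnames(genes_gr)),
      start = GenomicRanges::start(genes_gr),
      end = GenomicRanges::end(genes_gr),
      strand = as.character(GenomicRanges::strand(genes_gr)),
      stringsAsFactors = FALSE)
  } else {
    ex <- gr[type == "exon"]
    d <- data.frame(gene_id = S4Vectors::mcols(ex)$gene_id,
                    chrom = as.character(GenomicRanges::seqnames(ex)),
                    start = GenomicRanges::start(ex),
                    end = GenomicRanges::end(ex),
                    strand = as.character(GenomicRanges::strand(ex)),
                    stringsAsFactors = FALSE)
    genes <- do.call(rbind, lapply(split(d, d$gene_id), function(g) {
      data.frame(gene_id = g$gene_id[1L], chrom = g$chrom[1L],
                 start = min(g$start), end = max(g$end),
                 strand = g$strand[1L], stringsAsFactors = FALSE)
    }))
    rownames(genes) <- NULL
  }
  ex <- gr[type == "exon"]
  juncs <- empty_annotated_junctions()
  if (length(ex)) {
    mce <- S4Vectors::mcols(ex)
    if (!"transcript_id" %in% colnames(mce))
      stop("parse error: GTF exon records lack a transcript_id attribute")
    d <- data.frame(tx = mce$transcript_id,
                    chrom = as.character(GenomicRanges::seqnames(ex)),
                    start = GenomicRanges::start(ex),
                    end = GenomicRanges::end(ex),
                    strand = as.character(GenomicRanges::strand(ex)),
                    stringsAsFactors = FALSE)
    d <- d[order(d$tx, d$start), ]
    same_tx <- d$tx[-1L] == d$tx[-nrow(d)]
    if (any(same_tx)) {
      i <- which(same_tx)
      juncs <- data.frame(chrom = d$chrom[i],
                          intron_start = d$end[i] + 1L,
                          intron_end = d$start[i + 1L] - 1L,
                          strand = d$strand[i],
                          stringsAsFactors = FALSE)
      juncs <- juncs[juncs$intron_start <= juncs$intron_end, , drop = FALSE]
      juncs <- unique(juncs)
      rownames(juncs) <- NULL
    }
  }
  list(genes = genes, junctions = juncs, junction_ids = junction_id(juncs))
}

empty_annotated_junctions <- function() {
  data.frame(chrom = character(), intron_start = integer(),
             intron_end = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Export junctions as BED intervals
#'
#' Converts 1-based inclusive intron coordinates to the BED 0-based
#' half-open convention (`chromStart = intron_start - 1`,
#' `chromEnd = intron_end`).
#'
#' @param junctions Junction data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_junction_bed <- function(junctions, path) {
  bed <- data.frame(junctions$chrom,
                    junctions$intron_start - 1L,
                    junctions$intron_end,
                    junction_id(junctions),
                    0L,
                    ifelse(junctions$strand %in% c("+", "-"),
                           junctions$strand, "."))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
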