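# AS structures: grouping of junctions sharing a splice site, and
# sub-junction usage quantification.

#' Identify alternatively spliced junctions
#'
#' An AS junction shares its intron start with another junction (which has a
#' different intron end) or shares its intron end with another junction
#' (different intron start) on the same chromosome, i.e. it has an
#' alternative 5' or 3' splice site. Grouping is purely by genomic
#' coordinate; strand is not consulted.
#'
#' @param junctions Junction data frame, deduplicated on
#'   (`chrom`, `intron_start`, `intron_end`).
#' @return The subset of `junctions` that are alternatively spliced, input
#'   order preserved.
#' @export
find_as_junctions <- function(junctions) {
  if (anyDuplicated(junction_id(junctions)))
    stop("junctions must be deduplicated on (chrom, intron_start, intron_end)")
  ks <- paste(junctions$chrom, junctions$intron_start)
  ke <- paste(junctions$chrom, junctions$intron_end)
  ns <- table(ks)
  ne <- table(ke)
  keep <- as.vector(ns[ks] > 1L) | as.vector(ne[ke] > 1L)
  junctions[keep, , drop = FALSE]
}

#' Group AS junctions into AS structures
#'
#' An AS structure is the set of junctions anchored at one shared splice
#' site: one start-anchored structure per intron start shared by >= 2
#' junctions and one end-anchored structure per shared intron end.
#' Sub-junctions are ordered by the non-anchor coordinate. A junction may
#' belong to one start-anchored and one end-anchored structure
#' simultaneously (e.g. the skip junction of a cassette exon).
#'
#' Anchor sides are genomic; whether the anchored site is the splice donor
#' or acceptor depends on strand and is resolved at classification time.
#'
#' @param junctions AS-junction data frame (see [find_as_junctions()]).
#' @param counts Numeric matrix of unique read counts with rownames equal
#'   to `junction_id(junctions)` (extra rows allowed) and one column per
#'   sample.
#' @return A list of `as_structure` objects, ordered by chromosome, anchor
#'   position and side. Each has fields `structure_id`, `chrom`, `strand`
#'   (consensus, `*` if mixed), `anchor_side` (`"start"` or `"end"`),
#'   `anchor_pos`, `junction_ids`, `junctions` (data frame rows) and
#'   `counts` (sub-junctions x samples).
#' @export
build_structures <- function(junctions, counts) {
  jid <- junction_id(junctions)
  if (anyDuplicated(jid)) stop("junctions must be deduplicated")
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    stop("`counts` must have junction ids as rownames")
  missing <- setdiff(jid, rownames(counts))
  if (length(missing))
    stop("counts missing for junction(s): ", paste(missing, collapse = ", "))
  structures <- list()
  for (side in c("start", "end")) {
    coord <- if (side == "start") junctions$intron_start else
      junctions$intron_end
    other <- if (side == "start") junctions$intron_end else
      junctions$intron_start
    key <- paste(junctions$chrom, coord)
    grp <- split(seq_len(nrow(junctions)), key)
    grp <- grp[lengths(grp) >= 2L]
    for (idx in grp) {
      idx <- idx[order(other[idx])]
      strands <- unique(junctions$strand[idx])
      strands <- setdiff(strands, "*")
      s <- list(
        structure_id = sprintf("%s:%d:%s", junctions$chrom[idx[1L]],
                               coord[idx[1L]], side),
        chrom = junctions$chrom[idx[1L]],
        strand = if (length(strands) == 1L) strands else "*",
        anchor_side = side,
        anchor_pos = coord[idx[1L]],
        junction_ids = jid[idx],
        junctions = junctions[idx, , drop = FALSE],
        counts = counts[jid[idx], , drop = FALSE])
      class(s) <- "as_structure"
      structures[[length(structures) + 1L]] <- s
    }
  }
  ord <- order(vapply(structures, function(s) s$chrom, character(1)),
               vapply(structures, function(s) s$anchor_pos, numeric(1)),
               vapply(structures, function(s) s$anchor_side, character(1)))
  structures[ord]
}

#' @export
print.as_structure <- function(x, ...) {
  cat(sprintf("AS structure %s (%s-anchored, strand %s): %d sub-junctions\n",
              x$structure_id, x$anchor_side, x$strand,
              length(x$junction_ids)))
  invisible(x)
}

#' Sub-junction usage of an AS structure
#'
#' Usage of sub-junction i in sample s is its read count divided by the
#' structure's total junction reads in that sample. Samples with zero total
#' reads have undefined usage (`NA`) and are flagged via `defined`.
#'
#' @param x An `as_structure`, or a counts matrix (sub-junctions x samples).
#' @return A `usage_profile`: list with `usage` (matrix of fractions;
#'   columns with zero totals are `NA`), `totals` (per-sample column sums),
#'   `defined` (logical per sample) and `structure_id`.
#' @export
compute_usage <- function(x) {
  counts <- if (inherits(x, "as_structure")) x$counts else as.matrix(x)
  if (any(counts < 0)) stop("counts must be non-negative")
  totals <- colSums(counts)
  usage <- sweep(counts, 2L, totals, "/")
  usage[, totals == 0] <- NA_real_
  out <- list(usage = usage, totals = totals, defined = totals > 0,
              structure_id = if (inherits(x, "as_structure")) x$structure_id
                             else NA_character_)
  class(out) <- "usage_profile"
  out
}

#' @export
print.usage_profile <- function(x, ...) {
  cat(sprintf("Usage profile (%d sub-junctions x %d samples, %d defined)\n",
              nrow(x$usage), ncol(x$usage), sum(x$defined)))
  invisible(x)
}

#' Pool sample counts by group
#'
#' Sums counts over member samples of each group (e.g. collapsing a
#' time-course into per-day pooled datasets). Usage downstream of pooling is
#' always computed from the summed counts, never by averaging per-sample
#' usage fractions.
#'
#' @param counts Counts matrix, junctions x samples.
#' @param grouping Vector over columns assigning each sample to exactly one
#'   group; group order follows first appearance.
#' @return Counts matrix with one column per group.
#' @export
pool_samples <- function(counts, grouping) {
  counts <- as.matrix(counts)
  if (length(grouping) != ncol(counts))
    stop("`grouping` must assign every sample column to exactly one group")
  if (anyNA(grouping))
    stop("`grouping` must assign every sample column to exactly one group")
  grouping <- factor(grouping, levels = unique(as.character(grouping)))
  pooled <- t(rowsum(t(counts), grouping))
  colnames(pooled) <- levels(grouping)
  pooled
}

#' Tabulate AS structures with per-sample counts and usage
#'
#' @param structures List of `as_structure` objects.
#' @return Data frame with one row per sub-junction: structure id, anchor,
#'   sub-junction coordinates, then per-sample count and usage columns.
#' @export
structure_table <- function(structures) {
  rows <- lapply(structures, function(s) {
    u <- compute_usage(s)
    cnt <- s$counts
    colnames(cnt) <- paste0("count.", colnames(cnt))
    usg <- u$usage
    colnames(usg) <- paste0("usage.", colnames(usg))
    data.frame(structure_id = s$structure_id,
               chrom = s$chrom,
               anchor_side = s$anchor_side,
               anchor_pos = s$anchor_pos,
               strand = s$strand,
               junction_id = s$junction_ids,
               intron_start = s$junctions$intron_start,
               intron_end = s$junctions$intron_end,
               cnt, usg,
               row.names = NULL, check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
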