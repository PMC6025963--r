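# Junction novelty, cross-sample presence sets, overlap statistics, and
# cassette-exon conservation / reading-frame summaries.

#' Classify junctions as annotated or novel
#'
#' Exact-coordinate lookup against an annotated-junction library (both
#' intron endpoints must match; no fuzzy matching). Junctions are assigned
#' to containing genes when gene models are supplied; the within-gene
#' report excludes intergenic junctions, which are retained in a separate
#' bucket via `in_gene = FALSE`.
#'
#' @param junctions Junction data frame.
#' @param annotation_library Character vector of annotated junction ids
#'   (`chrom:start-end`), or the list returned by [read_gtf_annotation()].
#' @param gene_models Optional gene-model data frame for the within-gene
#'   restriction (see [assign_to_gene()]).
#' @return Data frame with one row per junction: `junction_id`, `status`
#'   (`"annotated"`/`"novel"`), `gene_id`, `in_gene`.
#' @export
classify_novelty <- function(junctions, annotation_library,
                             gene_models = NULL) {
  if (is.list(annotation_library) &&
      !is.null(annotation_library$junction_ids))
    annotation_library <- annotation_library$junction_ids
  jid <- junction_id(junctions)
  status <- ifelse(jid %in% annotation_library, "annotated", "novel")
  if (is.null(gene_models)) {
    gene_id <- rep(NA_character_, length(jid))
    in_gene <- rep(NA, length(jid))
  } else {
    asg <- assign_to_gene(junctions, gene_models)
    gene_id <- asg$gene_id
    in_gene <- !is.na(asg$gene_id)
  }
  data.frame(junction_id = jid, status = status, gene_id = gene_id,
             in_gene = in_gene, stringsAsFactors = FALSE)
}

#' Presence/absence matrix of junctions across samples
#'
#' @param junction_sets_by_sample Named list of junction-id character
#'   vectors, one per sample.
#' @return Binary matrix with one row per sample and one column per
#'   junction in the union, 1 when the junction was identified in the
#'   sample. Supports set-algebra queries via ordinary matrix operations.
#' @export
presence_matrix <- function(junction_sets_by_sample) {
  all_j <- sort(unique(unlist(junction_sets_by_sample)))
  m <- vapply(junction_sets_by_sample,
              function(s) as.integer(all_j %in% s),
              integer(length(all_j)))
  m <- t(matrix(m, nrow = length(all_j),
                dimnames = list(all_j, names(junction_sets_by_sample))))
  m
}

#' Hypergeometric overlap test
#'
#' Exact tail probability for the overlap `k` of a set of size `K` and a
#' set of size `n` drawn from a universe of size `N`. The direction is
#' explicit: `"lower"` (depletion, `P(X <= k)`) is the default, matching a
#' smaller-than-expected overlap; `"upper"` gives enrichment
#' (`P(X >= k)`). The universe size must be supplied explicitly and is
#' echoed in the result for reproducibility.
#'
#' @param N Universe size.
#' @param K,n Sizes of the two sets.
#' @param k Observed overlap.
#' @param tail `"lower"` (depletion) or `"upper"` (enrichment).
#' @return List of class `overlap_test`: `p_value`, `tail`, `N`, `K`, `n`,
#'   `k`, and `expected` overlap.
#' @export
hypergeom_overlap <- function(N, K, n, k, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  if (K > N || n > N || k > min(K, n) || k < 0 || any(c(N, K, n) < 0))
    stop("inconsistent set sizes: need 0 <= k <= min(K, n) <= N")
  p <- if (tail == "upper")
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  else
    stats::phyper(k, K, N - K, n)
  structure(list(p_value = p, tail = tail, N = N, K = K, n = n, k = k,
                 expected = K * n / N),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "Hypergeometric overlap (%s tail): k = %d (expected %.2f), p = %.3g\n",
    x$tail, x$k, x$expected, x$p_value))
  invisible(x)
}

#' Reading-frame preservation of an exon
#'
#' An alternative exon preserves the reading frame when its length
#' (`end - start + 1`, 1-based inclusive) is divisible by 3.
#'
#' @param start,end Exon interval (1-based inclusive); vectors allowed.
#' @return Logical vector.
#' @export
frame_preservation <- function(start, end) {
  if (any(end < start)) stop("exon end before start")
  ((end - start + 1L) %% 3L) == 0L
}

#' Mean per-base conservation over an exon
#'
#' Arithmetic mean of per-base scores (e.g. PhastCons) over the covered
#' bases of the interval, with the covered fraction reported. Zero covered
#' bases yield an undefined (flagged) result.
#'
#' @param start,end Exon interval (1-based inclusive).
#' @param scores Data frame with columns `pos` and `score` (plain per-base
#'   track, one row per covered base), or a numeric vector named by
#'   position.
#' @return List with `mean` (`NA` when no base is covered), `coverage`
#'   fraction in `[0, 1]`, and `n_bases`.
#' @export
mean_conservation <- function(start, end, scores) {
  if (end < start) stop("exon end before start")
  if (is.data.frame(scores)) {
    pos <- scores$pos
    val <- scores$score
  } else {
    pos <- as.numeric(names(scores))
    val <- as.numeric(scores)
  }
  sel <- pos >= start & pos <= end
  len <- end - start + 1
  n <- sum(sel)
  list(mean = if (n > 0) mean(val[sel]) else NA_real_,
       coverage = n / len, n_bases = n)
}

#' Compare two score distributions (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U test: exact when the combined sample size is
#' at most 20 and there are no ties, otherwise the normal approximation
#' with tie correction.
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @return List with `p_value`, `statistic` (U for the first sample) and
#'   `method`.
#' @export
compare_distributions <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L)
    stop("both samples must be non-empty")
  n <- length(values_a) + length(values_b)
  ties <- anyDuplicated(c(values_a, values_b)) > 0L
  exact <- n <= 20L && !ties
  w <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = exact, correct = TRUE))
  list(p_value = w$p.value, statistic = unname(w$statistic),
       method = if (exact) "exact" else "normal approximation")
}
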