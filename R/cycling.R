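# Time-of-day cycling detection for sub-junction usage: F24 spectral-power
# score, JTK-style exact Kendall-tau permutation test against cosine
# references, Fourier phase estimation, and the combined detector.

#' F24 spectral-power score
#'
#' Fraction of a series' non-DC spectral power carried by the one-cycle-
#' per-period (24 h) Fourier component: `|X_1|^2 / sum_k |X_k|^2` over
#' `k = 1..floor(N/2)` (DC excluded, Nyquist included). The score is 1 for
#' a pure 24 h cosine sampled on the grid, 0 for a constant series (by
#' convention), and invariant to adding a constant or positive scaling.
#' The series must hold `N >= 4` equally spaced values covering exactly one
#' period.
#'
#' @param series Numeric vector of `N >= 4` values.
#' @param timepoints Optional sampling times used only to validate equal
#'   spacing.
#' @return F24 score in `[0, 1]`.
#' @export
f24_score <- function(series, timepoints = NULL) {
  n <- length(series)
  if (n < 4L) stop("F24 requires at least 4 equally spaced samples")
  if (!all(is.finite(series))) stop("series must be finite")
  if (!is.null(timepoints)) .check_equal_spacing(timepoints, n)
  if (max(series) - min(series) < .Machine$double.eps * 100) return(0)
  x <- stats::fft(series)
  pw <- Mod(x[2:(n %/% 2 + 1L)])^2
  tot <- sum(pw)
  if (tot <= 0) return(0)
  pw[1L] / tot
}

.check_equal_spacing <- function(timepoints, n) {
  if (length(timepoints) != n)
    stop("timepoints must match the series length")
  d <- diff(timepoints)
  if (any(abs(d - d[1L]) > 1e-8))
    stop("series must be equally spaced")
  invisible(TRUE)
}

#' Estimate peak phase by Fourier transformation
#'
#' Phase of the one-cycle-per-period DFT component, mapped to the hour at
#' which the fitted cosine peaks, in `[0, period)`. Shifting the series
#' circularly by k grid steps shifts the phase by k grid spacings.
#'
#' @param series Numeric vector sampled at `timepoints` (one full period).
#' @param timepoints Sampling times in hours (default ZT 0,4,...,20).
#' @param period Period in hours (default 24).
#' @return Peak hour in `[0, period)`, or `NA` (flagged via attribute
#'   `defined`) when the fundamental has zero amplitude.
#' @export
estimate_phase <- function(series, timepoints = seq(0, 20, by = 4),
                           period = 24) {
  n <- length(series)
  if (n < 4L) stop("phase estimation requires at least 4 samples")
  .check_equal_spacing(timepoints, n)
  if (abs(n * diff(timepoints)[1L] - period) > 1e-8)
    stop("series must cover exactly one period")
  x1 <- stats::fft(series)[2L]
  if (Mod(x1) < .Machine$double.eps * 100 * max(1, max(abs(series)))) {
    out <- NA_real_
    attr(out, "defined") <- FALSE
    return(out)
  }
  phase <- (timepoints[1L] - Arg(x1) * period / (2 * pi)) %% period
  attr(phase, "defined") <- TRUE
  phase
}

# ---- JTK-style rhythmicity test -------------------------------------------

.jtk_cache <- new.env(parent = emptyenv())

.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    block <- cbind(rep(k, rows), ifelse(sub >= k, sub + 1L, sub))
    out[r + seq_len(rows), ] <- block
    r <- r + rows
  }
  out
}

.tie_term <- function(x) {
  t <- table(x)
  sum(t * (t - 1) / 2)
}

# Kendall tau-b via pairwise signs (shared by observed and null path).
.tau_b <- function(x, y, pairs = utils::combn(length(x), 2L)) {
  i <- pairs[1L, ]; j <- pairs[2L, ]
  num <- sum(sign(x[j] - x[i]) * sign(y[j] - y[i]))
  n0 <- length(i)
  den <- sqrt((n0 - .tie_term(x)) * (n0 - .tie_term(y)))
  if (den == 0) return(NA_real_)
  num / den
}

# Exact permutation null of tau-b for the value multiset `values` against a
# fixed reference. Returns the vector of tau over all n! orderings.
.tau_null <- function(values, ref) {
  n <- length(values)
  pairs <- utils::combn(n, 2L)
  i <- pairs[1L, ]; j <- pairs[2L, ]
  rs <- sign(ref[j] - ref[i])
  P <- .all_perms(n)
  V <- matrix(values[P], nrow(P), n)
  S <- sign(V[, j, drop = FALSE] - V[, i, drop = FALSE])
  num <- as.vector(S %*% rs)
  n0 <- ncol(pairs)
  den <- sqrt((n0 - .tie_term(values)) * (n0 - .tie_term(ref)))
  num / den
}

.jtk_exact_p <- function(series, ref, tau_obs) {
  n <- length(series)
  tiefree <- .tie_term(series) == 0
  if (tiefree) {
    key <- paste0("n", n, ":", paste(rank(ref), collapse = ","))
    null <- .jtk_cache[[key]]
    if (is.null(null)) {
      null <- .tau_null(seq_len(n), ref)
      assign(key, null, envir = .jtk_cache)
    }
  } else {
    null <- .tau_null(series, ref)
  }
  mean(null >= tau_obs - 1e-12)
}

#' JTK-style rhythmicity test (Kendall tau against cosine references)
#'
#' For each candidate phase on the timepoint grid, Kendall's tau-b is
#' computed between the observed series and a cosine reference of the given
#' period peaking at that phase. Each phase's p-value is the upper-tail
#' probability of tau under the null that all orderings of the series are
#' equally likely: exact by full permutation enumeration for series of
#' length <= 7 (tie-free series use a cached null; tied series are
#' enumerated directly), and the tie-corrected normal approximation
#' otherwise. The reported p-value is the Bonferroni-adjusted minimum over
#' phases.
#'
#' @param series Numeric vector; length must be a multiple of
#'   `length(timepoints)` (replicate days are arranged timepoint-major,
#'   i.e. the timepoint grid repeats per day).
#' @param timepoints Timepoint grid in hours (default ZT 0,4,...,20).
#' @param period Reference period in hours (default 24; no period search).
#' @param phases Candidate peak phases (default: the timepoint grid).
#' @return List with `p_value` (Bonferroni over phases), `best_phase`
#'   (phase of maximal tau; ties broken by phase order), `tau` and
#'   `phase_p` (per-phase values).
#' @export
jtk_test <- function(series, timepoints = seq(0, 20, by = 4), period = 24,
                     phases = timepoints) {
  n <- length(series)
  if (n %% length(timepoints) != 0L)
    stop("series length must be a multiple of the number of timepoints")
  if (!all(is.finite(series))) stop("series must be finite")
  tp <- rep(timepoints, n %/% length(timepoints))
  if (max(series) - min(series) < .Machine$double.eps * 100) {
    return(list(p_value = 1, best_phase = NA_real_,
                tau = rep(NA_real_, length(phases)),
                phase_p = rep(1, length(phases))))
  }
  pairs <- utils::combn(n, 2L)
  taus <- numeric(length(phases))
  ps <- numeric(length(phases))
  for (k in seq_along(phases)) {
    ref <- cos(2 * pi * (tp - phases[k]) / period)
    ref <- round(ref, 10)  # stabilise ties in the reference grid
    taus[k] <- .tau_b(series, ref, pairs)
    if (is.na(taus[k])) {
      ps[k] <- 1
      next
    }
    if (n <= 7L) {
      ps[k] <- .jtk_exact_p(series, ref, taus[k])
    } else {
      ps[k] <- suppressWarnings(
        stats::cor.test(series, ref, method = "kendall",
                        alternative = "greater", exact = FALSE)$p.value)
    }
  }
  best <- which.max(taus)
  list(p_value = min(1, length(phases) * min(ps)),
       best_phase = phases[best],
       tau = taus, phase_p = ps)
}

#' Usage fold change across timepoints
#'
#' `max / min` of per-timepoint usage (replica-averaged; undefined
#' timepoints are excluded). Callers are expected to pseudocount the counts
#' before forming usage when totals are small, so the ratio is finite.
#'
#' @param usage_by_timepoint Numeric vector of per-timepoint usage values
#'   (`NA` = undefined).
#' @return Fold change `>= 1`, or `NA` when every timepoint is undefined.
#' @export
usage_fold_change <- function(usage_by_timepoint) {
  u <- usage_by_timepoint[!is.na(usage_by_timepoint)]
  if (length(u) == 0L) return(NA_real_)
  if (min(u) <= 0) return(Inf)
  max(u) / min(u)
}

#' Detect cycling sub-junction usage across a time-course design
#'
#' Applies the per-replica read filter (more than `min_reads` unique reads
#' in at least one timepoint within each replicate day), builds AS
#' structures on the filtered junction set, and evaluates for every
#' sub-junction the per-timepoint usage series of replica-summed counts
#' with the F24 score, the JTK test, the usage fold change (pseudocounted)
#' and the Fourier phase. A sub-junction is called cycling by F24 when
#' `F24 > f24_cutoff`, fold change `> fold_cutoff` and the structure has
#' more than `min_reads` total junction reads at one or more timepoints in
#' each replicate day; by JTK when `p < jtk_alpha` with the same fold and
#' read gates. A structure is cycling when any sub-junction passes either
#' detector.
#'
#' @param junctions Junction catalog data frame.
#' @param counts Counts matrix (junctions x samples), rownames =
#'   junction ids.
#' @param sample_info Data frame with columns `sample` (matching
#'   `colnames(counts)`), `day` (replicate day) and `timepoint` (hours).
#' @param period Period in hours (default 24).
#' @param min_reads Read-support threshold (default 10, strict).
#' @param f24_cutoff,fold_cutoff,jtk_alpha Detector gates (defaults 0.5,
#'   1.5, 0.05).
#' @return Data frame with one row per sub-junction: structure and junction
#'   ids, `f24`, `jtk_p`, `fold_change`, `phase`, `mean_reads_ok`,
#'   `cycling_f24`, `cycling_jtk`, `cycling` (either detector) and
#'   `structure_cycling` (any sub-junction of the structure).
#' @export
run_cycling <- function(junctions, counts, sample_info, period = 24,
                        min_reads = 10, f24_cutoff = 0.5,
                        fold_cutoff = 1.5, jtk_alpha = 0.05) {
  counts <- as.matrix(counts)
  if (!all(sample_info$sample %in% colnames(counts)))
    stop("sample_info does not match the count matrix columns")
  counts <- counts[, sample_info$sample, drop = FALSE]
  timepoints <- sort(unique(sample_info$timepoint))
  jid <- junction_id(junctions)
  keep <- filter_by_support(counts[jid, , drop = FALSE], min_reads,
                            mode = "per-replica-any-timepoint",
                            replicas = sample_info$day)
  asj <- find_as_junctions(junctions[keep, , drop = FALSE])
  if (nrow(asj) == 0L) return(empty_cycling_table())
  structures <- build_structures(asj, counts)
  tp_group <- factor(sample_info$timepoint, levels = timepoints)
  rows <- list()
  for (s in structures) {
    totals <- colSums(s$counts)
    reads_ok <- all(vapply(split(totals, sample_info$day),
                           function(v) any(v > min_reads), logical(1)))
    pooled <- pool_samples(s$counts, tp_group)   # summed across days
    ptot <- colSums(pooled)
    m <- nrow(pooled)
    usage <- sweep(pooled, 2L, ptot, "/")
    usage[, ptot == 0] <- NA_real_
    usage_fc <- sweep(pooled + 0.5, 2L, ptot + 0.5 * m, "/")
    for (i in seq_len(m)) {
      u <- usage[i, ]
      complete <- !anyNA(u)
      f24 <- if (complete) f24_score(u, timepoints) else NA_real_
      ph <- if (complete) estimate_phase(u, timepoints, period) else
        NA_real_
      jp <- if (complete) jtk_test(u, timepoints, period)$p_value else
        NA_real_
      fc <- usage_fold_change(usage_fc[i, ])
      cyc_f24 <- isTRUE(f24 > f24_cutoff && fc > fold_cutoff && reads_ok)
      cyc_jtk <- isTRUE(jp < jtk_alpha && fc > fold_cutoff && reads_ok)
      rows[[length(rows) + 1L]] <- data.frame(
        structure_id = s$structure_id, junction_id = s$junction_ids[i],
        chrom = s$chrom, strand = s$strand,
        f24 = f24, jtk_p = jp, fold_change = fc,
        phase = as.numeric(ph), mean_reads_ok = reads_ok,
        cycling_f24 = cyc_f24, cycling_jtk = cyc_jtk,
        cycling = cyc_f24 || cyc_jtk, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  agg <- tapply(res$cycling, res$structure_id, any)
  res$structure_cycling <- as.vector(agg[res$structure_id])
  res
}

empty_cycling_table <- function() {
  data.frame(structure_id = character(), junction_id = character(),
             chrom = character(), strand = character(), f24 = numeric(),
             jtk_p = numeric(), fold_change = numeric(), phase = numeric(),
             mean_reads_ok = logical(), cycling_f24 = logical(),
             cycling_jtk = logical(), cycling = logical(),
             structure_cycling = logical(), stringsAsFactors = FALSE)
}
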