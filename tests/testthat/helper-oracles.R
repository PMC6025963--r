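# Independent oracles: hand-coded reference implementations kept separate
# from the package's code paths. Used by the unit tests and by
# scripts/acceptance.R.

# ---- splice-graph classification oracle -----------------------------------
# Direct predicate-based labelling of every AS structure in a junction set
# (single chromosome), without the package's graph machinery.

oracle_structures <- function(jn) {
  res <- list()
  for (side in c("start", "end")) {
    coord <- if (side == "start") jn$intron_start else jn$intron_end
    other <- if (side == "start") jn$intron_end else jn$intron_start
    for (v in sort(unique(coord))) {
      idx <- which(coord == v)
      if (length(idx) >= 2L) {
        idx <- idx[order(other[idx])]
        res[[length(res) + 1L]] <- list(side = side, anchor = v, idx = idx)
      }
    }
  }
  res
}

oracle_classify <- function(jn, strand = "+") {
  sts <- oracle_structures(jn)
  if (!length(sts))
    return(stats::setNames(character(0), character(0)))
  nsub <- vapply(sts, function(s) length(s$idx), 0L)
  partners <- lapply(seq_along(sts), function(i) {
    which(vapply(seq_along(sts), function(j) {
      j != i && length(intersect(sts[[i]]$idx, sts[[j]]$idx)) > 0L
    }, TRUE))
  })
  iso <- which(nsub == 2L & lengths(partners) == 0L)
  labels <- rep(NA_character_, length(sts))

  # mutually exclusive exons: pair isolated structures greedily by anchor
  used <- rep(FALSE, length(sts))
  ord <- iso[order(vapply(sts[iso], function(s) s$anchor, 0))]
  for (i in ord) {
    if (used[i] || sts[[i]]$side != "start") next
    for (j in ord) {
      if (used[j] || sts[[j]]$side != "end") next
      a <- sort(jn$intron_end[sts[[i]]$idx])
      b <- sort(jn$intron_start[sts[[j]]$idx])
      e1 <- c(a[1L] + 1L, b[1L] - 1L)
      e2 <- c(a[2L] + 1L, b[2L] - 1L)
      geom <- e1[1L] <= e1[2L] && e2[1L] <= e2[2L] && e1[2L] < e2[1L]
      joining <- any(jn$intron_start - 1L >= e1[1L] &
                       jn$intron_start - 1L <= e1[2L] &
                       jn$intron_end + 1L >= e2[1L] &
                       jn$intron_end + 1L <= e2[2L])
      if (geom && !joining) {
        labels[c(i, j)] <- "MXE"
        used[c(i, j)] <- TRUE
        break
      }
    }
  }

  for (i in seq_along(sts)) {
    if (!is.na(labels[i])) next
    s <- sts[[i]]
    if (nsub[i] == 2L && length(partners[[i]]) == 0L) {
      labels[i] <- if (!strand %in% c("+", "-")) "A5SS/A3SS-unoriented"
      else if ((s$side == "start") == (strand == "+")) "A3SS"
      else "A5SS"
      next
    }
    ok <- FALSE
    if (nsub[i] == 2L && length(partners[[i]]) == 1L) {
      p <- partners[[i]][1L]
      if (nsub[p] == 2L && length(partners[[p]]) == 1L &&
          partners[[p]][1L] == i && sts[[p]]$side != s$side &&
          length(intersect(s$idx, sts[[p]]$idx)) == 1L) {
        sd <- if (s$side == "start") s else sts[[p]]
        se <- if (s$side == "end") s else sts[[p]]
        shared <- intersect(sd$idx, se$idx)
        if (jn$intron_start[shared] == sd$anchor &&
            jn$intron_end[shared] == se$anchor) {
          il <- setdiff(sd$idx, shared)
          ir <- setdiff(se$idx, shared)
          a1 <- jn$intron_end[il]
          d2 <- jn$intron_start[ir]
          ok <- a1 < se$anchor && d2 > sd$anchor && a1 + 1L <= d2 - 1L
        }
      }
    }
    labels[i] <- if (ok) "SE" else "Composite"
  }
  names(labels) <- vapply(sts, function(s)
    sprintf("%s:%d:%s", jn$chrom[1L], s$anchor, s$side), character(1))
  labels
}

# Package-side labels in the same keyed form, via classify_events().
package_classify <- function(jn, counts = NULL) {
  asj <- find_as_junctions(jn)
  if (nrow(asj) == 0L)
    return(stats::setNames(character(0), character(0)))
  if (is.null(counts))
    counts <- matrix(1L, nrow(asj), 2L,
                     dimnames = list(junction_id(asj), c("s1", "s2")))
  sts <- build_structures(asj, counts)
  ev <- classify_events(sts, catalog = jn)
  out <- stats::setNames(character(0), character(0))
  for (e in ev) {
    if (e$pattern == "IR") next
    for (sid in e$structure_ids) out[sid] <- e$pattern
  }
  out
}

# All junction subsets of size <= max_size over a fixed splice-site grid.
topology_cases <- function(n_sites = 6L, max_size = 5L, spacing = 10L) {
  sites <- seq_len(n_sites) * spacing
  pairs <- t(utils::combn(n_sites, 2L))
  pool <- data.frame(chrom = "chrT",
                     intron_start = sites[pairs[, 1L]],
                     intron_end = sites[pairs[, 2L]],
                     strand = "+", motif = "GT/AG", annotated = TRUE,
                     stringsAsFactors = FALSE)
  cases <- list()
  for (k in seq_len(max_size)) {
    sel <- utils::combn(nrow(pool), k)
    for (c_i in seq_len(ncol(sel))) {
      cases[[length(cases) + 1L]] <- pool[sel[, c_i], , drop = FALSE]
    }
  }
  cases
}

# ---- Kendall tau / JTK oracle ---------------------------------------------

naive_tau_b <- function(x, y) {
  n <- length(x)
  num <- 0; tx <- 0; ty <- 0; n0 <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    n0 <- n0 + 1
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    num <- num + dx * dy
    if (dx == 0) tx <- tx + 1
    if (dy == 0) ty <- ty + 1
  }
  num / sqrt((n0 - tx) * (n0 - ty))
}

naive_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- naive_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

# Exhaustive-permutation JTK p-value (upper tail per phase, Bonferroni).
naive_jtk <- function(series, timepoints = seq(0, 20, by = 4),
                      period = 24, phases = timepoints) {
  P <- naive_perms(length(series))
  ps <- vapply(phases, function(ph) {
    ref <- round(cos(2 * pi * (timepoints - ph) / period), 10)
    obs <- naive_tau_b(series, ref)
    null <- apply(P, 1L, function(ix) naive_tau_b(series[ix], ref))
    mean(null >= obs - 1e-12)
  }, 0)
  list(p_value = min(1, length(phases) * min(ps)), phase_p = ps)
}

# ---- misc oracles ---------------------------------------------------------

brute_force_gene <- function(junction, genes) {
  hit <- genes$chrom == junction$chrom &
    genes$start <= junction$intron_start - 1L &
    genes$end >= junction$intron_end + 1L
  sort(genes$gene_id[hit])
}

circular_error <- function(a, b, period = 24) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

dft_f24 <- function(x) {
  # direct DFT sum, no fft()
  n <- length(x)
  ks <- seq_len(n %/% 2)
  pw <- vapply(ks, function(k) {
    re <- sum(x * cos(-2 * pi * k * (seq_len(n) - 1) / n))
    im <- sum(x * sin(-2 * pi * k * (seq_len(n) - 1) / n))
    re^2 + im^2
  }, 0)
  pw[1L] / sum(pw)
}
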