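# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

random_junctions <- function(n, chroms = c("chr2L", "chr3R"),
                             max_pos = 5000L) {
  repeat {
    start <- sample.int(max_pos, n, replace = TRUE)
    len <- sample(50:500, n, replace = TRUE)
    jn <- data.frame(
      chrom = sample(chroms, n, replace = TRUE),
      intron_start = start,
      intron_end = start + len,
      strand = sample(c("+", "-", "*"), n, replace = TRUE,
                      prob = c(0.45, 0.45, 0.1)),
      motif = sample(c("GT/AG", "CT/AC", "non-canonical"), n,
                     replace = TRUE),
      annotated = sample(c(TRUE, FALSE), n, replace = TRUE),
      stringsAsFactors = FALSE)
    if (!anyDuplicated(junction_id(jn))) return(jn)
  }
}

random_sj_table <- function(n) {
  jn <- random_junctions(n)
  jn$unique_reads <- sample.int(1000L, n, replace = TRUE) - 1L
  jn$multi_reads <- sample.int(50L, n, replace = TRUE) - 1L
  jn$max_overhang <- sample.int(100L, n, replace = TRUE)
  jn$motif <- sample(c("non-canonical", "GT/AG", "CT/AC", "GC/AG",
                       "CT/GC", "AT/AC", "GT/AT"), n, replace = TRUE)
  jn
}

random_counts <- function(junctions, samples, lambda = 50) {
  m <- matrix(stats::rpois(nrow(junctions) * length(samples), lambda),
              nrow(junctions), length(samples),
              dimnames = list(junction_id(junctions), samples))
  m
}

# Counts for a two-group beta-binomial (m = 2) or Dirichlet-multinomial
# structure draw, used in calibration and power tests.
draw_dm_structure <- function(psi, reps, depth = 100, concentration = 60,
                              nb_dispersion = 0.15) {
  if (length(psi) == 1L) psi <- c(psi, 1 - psi)
  m <- length(psi)
  sapply(seq_len(reps), function(j) {
    total <- stats::rnbinom(1L, mu = depth, size = 1 / nb_dispersion)
    if (m == 2L) {
      p <- stats::rbeta(1L, concentration * psi[1L],
                        concentration * (1 - psi[1L]))
      k <- stats::rbinom(1L, total, p)
      c(k, total - k)
    } else {
      g <- stats::rgamma(m, shape = concentration * psi)
      as.integer(stats::rmultinom(1L, total, g / sum(g)))
    }
  })
}

# A deterministic cassette-exon fixture: inclusion junctions (201,300) and
# (401,500), skip junction (201,500), on the given chromosome.
cassette_junctions <- function(chrom = "chr2L", strand = "+",
                               offset = 0L) {
  data.frame(chrom = chrom,
             intron_start = offset + c(201L, 401L, 201L),
             intron_end = offset + c(300L, 500L, 500L),
             strand = strand, motif = "GT/AG", annotated = TRUE,
             stringsAsFactors = FALSE)
}
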