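zt6 <- seq(0, 20, by = 4)

test_that("F24 is 1 on a pure 24 h cosine and 0 on constants", {
  expect_equal(f24_score(cos(2 * pi * zt6 / 24), zt6), 1)
  expect_equal(f24_score(rep(0.42, 6)), 0)
  expect_error(f24_score(c(1, 2, 3)), "at least 4")
  expect_error(f24_score(1:6, timepoints = c(0, 4, 8, 12, 17, 20)),
               "equally spaced")
})

test_that("F24 equals the direct DFT power ratio on random series", {
  set.seed(2)
  for (rep in 1:200) {
    x <- runif(6)
    expect_equal(f24_score(x), dft_f24(x), tolerance = 1e-12)
  }
  x8 <- runif(8)
  expect_equal(f24_score(x8), dft_f24(x8), tolerance = 1e-12)
})

test_that("F24 is invariant to affine changes with positive scale", {
  set.seed(6)
  for (rep in 1:20) {
    x <- runif(6)
    a <- runif(1, -5, 5)
    b <- runif(1, 0.1, 10)
    expect_equal(f24_score(a + b * x), f24_score(x), tolerance = 1e-9)
  }
})

test_that("phase estimation is exact on cosines and equivariant to shifts", {
  x <- cos(2 * pi * (zt6 - 8) / 24)
  expect_equal(as.numeric(estimate_phase(x, zt6)), 8)
  x2 <- cos(2 * pi * (zt6 - 12) / 24)
  expect_equal(as.numeric(estimate_phase(x2, zt6)), 12)
  # circular shift by k grid steps shifts phase by 4k hours mod 24
  set.seed(10)
  y <- 0.5 + 0.3 * cos(2 * pi * (zt6 - 4) / 24) + rnorm(6, sd = 0.03)
  p0 <- as.numeric(estimate_phase(y, zt6))
  for (k in 1:5) {
    ys <- y[((seq_len(6) - 1 + k) %% 6) + 1]  # x shifted left by k
    pk <- as.numeric(estimate_phase(ys, zt6))
    expect_equal(circular_error(pk, (p0 - 4 * k) %% 24), 0,
                 tolerance = 1e-6)
  }
  flat <- estimate_phase(rep(1, 6), zt6)
  expect_true(is.na(flat))
  expect_false(attr(flat, "defined"))
})

test_that("JTK p-values equal exhaustive permutation enumeration", {
  set.seed(77)
  for (rep in 1:8) {
    x <- round(runif(6), 3)
    if (anyDuplicated(x)) next
    got <- jtk_test(x, zt6)
    want <- naive_jtk(x, zt6)
    expect_equal(got$phase_p, want$phase_p, tolerance = 1e-12)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  }
})

test_that("a rank-perfect cosine match attains the minimal exact p", {
  ref <- cos(2 * pi * zt6 / 24)
  x <- rank(ref) + seq(0.001, 0.006, by = 0.001)  # tie-free, same order
  got <- jtk_test(x, zt6)
  # ties in the reference leave 4 permutations at the maximal tau
  expect_equal(min(got$phase_p), 4 / 720)
  expect_equal(got$best_phase, 0)
  # reversed series: same p, phase shifted by 12 h
  rev_got <- jtk_test(-x, zt6)
  expect_equal(rev_got$p_value, got$p_value)
  expect_equal(rev_got$best_phase, 12)
})

test_that("tied series and constant series are handled", {
  x <- c(0.5, 0.5, 0.1, 0.1, 0.3, 0.3)
  got <- jtk_test(x, zt6)
  want <- naive_jtk(x, zt6)
  expect_equal(got$phase_p, want$phase_p, tolerance = 1e-12)
  expect_equal(jtk_test(rep(0.2, 6), zt6)$p_value, 1)
})

test_that("usage fold change follows max/min over defined timepoints", {
  expect_equal(usage_fold_change(c(0.2, 0.2, 0.4, 0.3, 0.2, 0.2)), 2)
  expect_equal(usage_fold_change(rep(0.3, 6)), 1)
  expect_equal(usage_fold_change(c(0.2, NA, 0.5, NA, 0.25, 0.25)), 2.5)
  expect_true(is.na(usage_fold_change(rep(NA_real_, 6))))
})

test_that("run_cycling gates by F24, JTK, fold change and read support", {
  set.seed(41)
  cfg <- sim_config(seed = 41, cycling_fraction = 0.5,
                    differential_fraction = 0)
  sim <- simulate_dataset(cfg)
  si <- sim$samples[sim$samples$condition == "DN1", ]
  res <- run_cycling(sim$junctions, sim$counts[, si$sample], si)
  expect_true(all(res$f24 >= 0 & res$f24 <= 1, na.rm = TRUE))
  expect_true(all(res$fold_change >= 1, na.rm = TRUE))
  expect_true(all(is.na(res$phase) | (res$phase >= 0 & res$phase < 24)))
  expect_equal(res$cycling_f24,
               !is.na(res$f24) & res$f24 > 0.5 &
                 res$fold_change > 1.5 & res$mean_reads_ok)
  expect_equal(res$cycling_jtk,
               !is.na(res$jtk_p) & res$jtk_p < 0.05 &
                 res$fold_change > 1.5 & res$mean_reads_ok)
  expect_equal(res$cycling, res$cycling_f24 | res$cycling_jtk)
  # structure flag is the union over sub-junctions
  for (sid in unique(res$structure_id)) {
    expect_equal(unique(res$structure_cycling[res$structure_id == sid]),
                 any(res$cycling[res$structure_id == sid]))
  }
})

test_that("a planted cycler failing the per-replica filter is excluded", {
  jn <- data.frame(chrom = "chr2L", intron_start = 100L,
                   intron_end = c(200L, 300L), strand = "+",
                   stringsAsFactors = FALSE)
  si <- data.frame(sample = sprintf("d%d_t%d", rep(1:2, each = 6),
                                    rep(zt6, 2)),
                   day = rep(1:2, each = 6),
                   timepoint = rep(zt6, 2), stringsAsFactors = FALSE)
  counts <- matrix(50L, 2, 12, dimnames = list(junction_id(jn), si$sample))
  counts[1, si$day == 2] <- 5L  # junction 1 never exceeds 10 on day 2
  res <- run_cycling(jn, counts, si)
  expect_false("chr2L:100-200" %in% res$junction_id)
  expect_equal(nrow(res), 0L)  # its partner alone forms no structure
})
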