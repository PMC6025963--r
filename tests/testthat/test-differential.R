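test_that("identical groups give delta 0 and a null p-value", {
  A <- cbind(c(80, 20), c(80, 20))
  res <- test_structure(A, A)
  expect_equal(res$delta_usage, 0)
  expect_gt(res$p_value, 0.9)
  expect_false(res$significant)
})

test_that("a strong single-replicate flip agrees with Fisher's exact test", {
  A <- cbind(c(90, 10))
  B <- cbind(c(10, 90))
  res <- test_structure(A, B)
  fisher <- stats::fisher.test(cbind(c(90, 10), c(10, 90)))$p.value
  expect_true(res$significant)
  # agreement within an order of magnitude on the log scale
  expect_lt(abs(log10(res$p_value) - log10(fisher)), 1)
})

test_that("group labels are exchangeable", {
  set.seed(8)
  for (rep in 1:5) {
    A <- draw_dm_structure(runif(1, 0.2, 0.8), 2)
    B <- draw_dm_structure(runif(1, 0.2, 0.8), 2)
    r1 <- test_structure(A, B)
    r2 <- test_structure(B, A)
    expect_equal(r1$delta_usage, r2$delta_usage)
    # the per-structure ML path is symmetric up to optimizer start order
    expect_equal(r1$p_value, r2$p_value, tolerance = 1e-3)
    # fixed-concentration path too
    r1 <- test_structure(A, B, theta = 60)
    r2 <- test_structure(B, A, theta = 60)
    expect_equal(r1$p_value, r2$p_value, tolerance = 1e-6)
  }
})

test_that("all-zero totals in one group are flagged untestable", {
  A <- cbind(c(50, 50))
  B <- cbind(c(0, 0))
  res <- test_structure(A, B)
  expect_true(res$untestable)
  expect_true(is.na(res$p_value))
})

test_that("multi-way structures are testable with df = m - 1", {
  set.seed(12)
  A <- draw_dm_structure(c(0.6, 0.3, 0.1), 3)
  B <- draw_dm_structure(c(0.2, 0.3, 0.5), 3)
  res <- test_structure(A, B)
  expect_equal(res$df, 2L)
  expect_lt(res$p_value, 0.05)
  expect_equal(res$delta_usage, max(abs(res$usage_a - res$usage_b)))
})

test_that("the pooled concentration estimator recovers the truth", {
  set.seed(99)
  groups <- rep(c("a", "b"), each = 2)
  sims <- replicate(400, {
    psi <- runif(1, 0.25, 0.75)
    cbind(draw_dm_structure(psi, 2), draw_dm_structure(psi, 2))
  }, simplify = FALSE)
  th <- estimate_concentration(sims, groups)
  expect_gt(th, 30)
  expect_lt(th, 120)  # truth is 60
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("power is monotone in the planted usage difference", {
  set.seed(14)
  power_at <- function(delta, n = 60) {
    hits <- 0L
    sims <- vector("list", n)
    for (i in seq_len(n)) {
      base <- runif(1, 0.2, 0.8 - delta)
      sims[[i]] <- list(A = draw_dm_structure(base, 2),
                        B = draw_dm_structure(base + delta, 2))
    }
    th <- estimate_concentration(
      lapply(sims, function(s) cbind(s$A, s$B)), rep(c("a", "b"), each = 2))
    mean(vapply(sims, function(s)
      test_structure(s$A, s$B, theta = th)$significant, TRUE))
  }
  p1 <- power_at(0.1)
  p2 <- power_at(0.2)
  p4 <- power_at(0.4)
  expect_true(p1 <= p2 + 0.1)  # allow Monte-Carlo slack
  expect_true(p2 <= p4 + 0.1)
  expect_gt(p4, 0.8)
})

test_that("run_differential filters, tests, classifies and gates", {
  set.seed(23)
  cfg <- sim_config(seed = 23, differential_fraction = 0.5,
                    cycling_fraction = 0)
  sim <- simulate_dataset(cfg)
  si <- sim$samples
  pair <- cfg$diff_pair
  pool_group <- function(cond) {
    cols <- si$sample[si$condition == cond]
    pool_samples(sim$counts[, cols],
                 paste0(cond, "_d", si$day[si$condition == cond]))
  }
  counts <- cbind(pool_group(pair[1]), pool_group(pair[2]))
  ga <- colnames(counts)[1:2]
  gb <- colnames(counts)[3:4]
  res <- run_differential(sim$junctions, counts, ga, gb)
  expect_true(all(res$delta_usage >= 0 & res$delta_usage <= 1,
                  na.rm = TRUE))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1, na.rm = TRUE))
  # significance gate is exactly delta > 0.10 & p <= 0.05
  expect_equal(res$significant,
               !res$untestable & res$delta_usage > 0.10 &
                 res$p_value <= 0.05)
  # planted differential structures are recovered
  tr <- sim$truth$trajectories
  diff_ev <- unique(tr$event_id[tr$differential])
  jmap <- stats::setNames(sim$junctions$event_id,
                          sim$junctions$junction_id)
  st_map <- lapply(build_structures(
    find_as_junctions(sim$junctions), sim$counts), function(s)
      unique(jmap[s$junction_ids]))
  names(st_map) <- vapply(build_structures(
    find_as_junctions(sim$junctions), sim$counts),
    `[[`, character(1), "structure_id")
  res$event <- vapply(res$structure_id, function(sid)
    stats::na.omit(st_map[[sid]])[1], character(1))
  recovered <- unique(res$event[res$significant])
  testable_diff <- intersect(diff_ev, res$event)
  expect_gt(length(intersect(recovered, testable_diff)) /
              max(1, length(testable_diff)), 0.8)
  expect_error(run_differential(sim$junctions, counts, ga, c(gb, ga[1])),
               "overlap")
})

test_that("junctions failing the pooled read filter never appear", {
  jn <- cassette_junctions()
  counts <- matrix(c(5, 50, 50,
                     5, 50, 50,
                     100, 100, 100,
                     100, 100, 100), nrow = 3,
                   dimnames = list(junction_id(jn),
                                   c("a1", "a2", "b1", "b2")))
  # junction 1 has pooled 10 reads in group a (not > 10): dropped, so the
  # start-anchored structure at 201 cannot form; the end-anchored
  # structure at 500 survives on the remaining two junctions
  res <- run_differential(jn, counts, c("a1", "a2"), c("b1", "b2"))
  expect_false("chr2L:201:start" %in% res$structure_id)
  expect_true("chr2L:500:end" %in% res$structure_id)
})
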