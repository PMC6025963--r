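test_that("planted topologies match their pattern by construction", {
  cfg <- sim_config(events_per_pattern = c(SE = 1, A5SS = 0, A3SS = 0,
                                           MXE = 1, IR = 0, Composite = 0),
                    background_genes = 0, seed = 2)
  truth <- simulate_genome(cfg)
  se_j <- truth$junctions[truth$junctions$event_id == "ev001", ]
  expect_equal(nrow(se_j), 3L)
  expect_equal(sort(se_j$role),
               sort(c("inclusion-left", "inclusion-right", "skip")))
  mxe_j <- truth$junctions[truth$junctions$event_id == "ev002", ]
  expect_equal(nrow(mxe_j), 4L)
})

test_that("the classifier reproduces every planted pattern label", {
  cfg <- sim_config(seed = 5)
  sim <- simulate_dataset(cfg)
  asj <- find_as_junctions(sim$junctions)
  st <- build_structures(asj, sim$counts)
  ev <- classify_events(st, boundary_counts = sim$boundary,
                        catalog = sim$junctions)
  jmap <- stats::setNames(sim$junctions$event_id,
                          sim$junctions$junction_id)
  hits <- 0L
  for (e in ev) {
    ids <- stats::na.omit(unique(jmap[unlist(e$roles)]))
    expect_length(ids, 1L)
    planted <- sim$truth$events$pattern[
      sim$truth$events$event_id == ids[1]]
    expect_equal(e$pattern, planted)
    hits <- hits + 1L
  }
  expect_equal(hits, sum(cfg$events_per_pattern))
})

test_that("identical seeds give identical datasets, different seeds differ", {
  cfg <- sim_config(seed = 11, background_genes = 5)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth$trajectories, s2$truth$trajectories)
  s3 <- simulate_dataset(sim_config(seed = 12, background_genes = 5))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("high-depth noise-free usage matches the planted trajectory", {
  cfg <- sim_config(seed = 3, depth = 1e5, nb_dispersion = 0,
                    concentration = Inf,
                    events_per_pattern = c(SE = 3, A5SS = 3, A3SS = 0,
                                           MXE = 0, IR = 0, Composite = 0),
                    background_genes = 0, cycling_fraction = 0,
                    differential_fraction = 0)
  sim <- simulate_dataset(cfg)
  tr <- sim$truth$trajectories
  jn <- sim$junctions
  for (ev in unique(jn$event_id)) {
    alt <- jn$junction_id[jn$event_id == ev & jn$group == "alt"][1]
    other <- jn$junction_id[jn$event_id == ev & jn$group == "other"][1]
    base <- tr$base[tr$event_id == ev][1]
    usage <- sim$counts[alt, 1] /
      (sim$counts[alt, 1] + sim$counts[other, 1])
    expect_equal(unname(usage), base, tolerance = 0.01)
  }
})

test_that("null count variance is consistent with the overdispersed model", {
  # amplitude 0, delta 0: per-sample usage variance across many draws
  # should match the beta-binomial prediction within Monte-Carlo error
  set.seed(55)
  psi <- 0.4; conc <- 60; depth <- 200
  draws <- replicate(3000, {
    k <- draw_dm_structure(psi, 1, depth = depth, concentration = conc,
                           nb_dispersion = 0.1)
    k[1] / sum(k)
  })
  v_obs <- var(draws)
  # Var(k/T) approx E[ psi(1-psi)(1+(T-1)rho)/T ] over the total T
  rho <- 1 / (conc + 1)
  tdist <- rnbinom(20000, mu = depth, size = 10)
  tdist <- tdist[tdist > 0]
  v_pred <- mean(psi * (1 - psi) * (1 + (tdist - 1) * rho) / tdist)
  expect_equal(v_obs, v_pred, tolerance = 0.15)
})

test_that("usage trajectories honor the [0.01, 0.99] clamp", {
  cfg <- sim_config(seed = 21, cycling_fraction = 1,
                    differential_fraction = 0.5)
  truth <- simulate_genome(cfg)
  tr <- truth$trajectories
  expect_true(all(tr$base + tr$amplitude <= 0.99))
  expect_true(all(tr$base - tr$amplitude >= 0.01))
})

test_that("truth tables round-trip and cover every junction", {
  cfg <- sim_config(seed = 7, background_genes = 4)
  sim <- simulate_dataset(cfg)
  d <- withr::local_tempdir()
  write_truth(sim$truth, d)
  back <- read_truth(d)
  expect_equal(back$events, sim$truth$events)
  expect_equal(back$junctions, sim$truth$junctions)
  expect_equal(back$trajectories, sim$truth$trajectories,
               tolerance = 1e-12)
  # every emitted junction is traceable to an event or background
  expect_true(all(!is.na(sim$junctions$event_id) |
                    sim$junctions$role == "constitutive"))
  # event counts per pattern equal the configuration
  got <- table(sim$truth$events$pattern)
  expect_equal(as.integer(got[names(cfg$events_per_pattern)]),
               unname(cfg$events_per_pattern))
})

test_that("written datasets are a faithful, annotated representation", {
  cfg <- sim_config(seed = 13, background_genes = 3,
                    events_per_pattern = c(SE = 2, A5SS = 1, A3SS = 1,
                                           MXE = 1, IR = 1, Composite = 1))
  sim <- simulate_dataset(cfg)
  d <- withr::local_tempdir()
  write_sim_dataset(sim, d)
  # SJ tables reload to the same counts
  s <- sim$samples$sample[5]
  tab <- read_sj_table(file.path(d, "samples", paste0(s, ".SJ.out.tab")))
  expect_equal(stats::setNames(tab$unique_reads, junction_id(tab)),
               sim$counts[junction_id(tab), s])
  # the GTF's junction library is exactly the non-novel catalog
  ann <- read_gtf_annotation(file.path(d, "annotation.gtf"))
  expect_setequal(ann$junction_ids,
                  sim$junctions$junction_id[!sim$junctions$novel])
  # annotated junctions all lie within their gene span
  asg <- assign_to_gene(ann$junctions, ann$genes)
  expect_true(all(!is.na(asg$gene_id)))
})
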