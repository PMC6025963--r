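classify_labels <- function(jn) package_classify(jn)

test_that("a cassette-exon component is classified SE with the internal exon", {
  jn <- cassette_junctions()
  counts <- random_counts(jn, "s1")
  st <- build_structures(jn, counts)
  ev <- classify_events(st)
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$pattern, "SE")
  expect_equal(unname(ev[[1]]$exon_coords),
               c(301L, 400L))
  expect_equal(ev[[1]]$roles$skip, "chr2L:201-500")
})

test_that("lone two-junction structures are oriented by side and strand", {
  mk <- function(strand, side) {
    jn <- if (side == "start")
      data.frame(chrom = "chr2L", intron_start = 100L,
                 intron_end = c(200L, 300L), strand = strand,
                 stringsAsFactors = FALSE)
    else
      data.frame(chrom = "chr2L", intron_start = c(100L, 150L),
                 intron_end = 300L, strand = strand,
                 stringsAsFactors = FALSE)
    st <- build_structures(jn, random_counts(jn, "s1"))
    orient_a5ss_a3ss(st[[1]])
  }
  expect_equal(mk("+", "start"), "A3SS")
  expect_equal(mk("-", "start"), "A5SS")
  expect_equal(mk("+", "end"), "A5SS")
  expect_equal(mk("-", "end"), "A3SS")
  expect_equal(mk("*", "start"), "A5SS/A3SS-unoriented")
})

test_that("mutually exclusive exons require disjoint exons and no joining junction", {
  mxe <- data.frame(chrom = "chr2L",
                    intron_start = c(201L, 201L, 401L, 601L),
                    intron_end = c(300L, 500L, 700L, 700L),
                    strand = "+", stringsAsFactors = FALSE)
  labels <- classify_labels(mxe)
  expect_equal(unname(labels), rep("MXE", 2))

  # adding the exon-joining junction (donor in exon 1, acceptor in exon 2)
  # merges the component and demotes it to Composite
  joined <- rbind(mxe,
                  data.frame(chrom = "chr2L", intron_start = 401L,
                             intron_end = 500L, strand = "+",
                             stringsAsFactors = FALSE))
  labels <- classify_labels(joined)
  expect_true(all(labels == "Composite"))
})

test_that("structures with three or more sub-junctions become Composite", {
  jn <- data.frame(chrom = "chr2L", intron_start = 100L,
                   intron_end = c(200L, 300L, 400L), strand = "+",
                   stringsAsFactors = FALSE)
  expect_equal(unname(classify_labels(jn)), "Composite")
})

test_that("every structure lands in exactly one event (partition)", {
  set.seed(31)
  for (rep in 1:10) {
    jn <- random_junctions(30, chroms = "chr2L", max_pos = 500L)
    asj <- find_as_junctions(jn)
    if (nrow(asj) == 0L) next
    st <- build_structures(asj, random_counts(asj, "s1"))
    ev <- classify_events(st, catalog = jn)
    assigned <- unlist(lapply(ev, `[[`, "structure_ids"))
    expect_equal(anyDuplicated(assigned), 0L)
    expect_setequal(assigned,
                    vapply(st, `[[`, character(1), "structure_id"))
  }
})

test_that("classification matches the predicate oracle on exhaustive topologies", {
  # all junction subsets of size <= 4 on a 6-site grid (size 5 is covered
  # by the acceptance suite)
  cases <- topology_cases(n_sites = 6L, max_size = 4L)
  n_checked <- 0L
  for (jn in cases) {
    got <- classify_labels(jn)
    want <- oracle_classify(jn)
    expect_identical(got[order(names(got))], want[order(names(want))])
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 15 + choose(15, 2) + choose(15, 3) +
                 choose(15, 4))
})

test_that("classification is invariant under translation and renaming", {
  set.seed(5)
  for (rep in 1:5) {
    jn <- random_junctions(20, chroms = "chr2L", max_pos = 400L)
    l1 <- classify_labels(jn)
    jn2 <- jn
    jn2$intron_start <- jn2$intron_start + 10000L
    jn2$intron_end <- jn2$intron_end + 10000L
    jn2$chrom <- "chrOther"
    l2 <- classify_labels(jn2)
    strip <- function(l) unname(l[order(names(l))])
    expect_identical(strip(l1), strip(l2))
  }
})

test_that("SE calls always nest inclusion junctions inside the skip span", {
  set.seed(17)
  for (rep in 1:20) {
    jn <- rbind(cassette_junctions(offset = 5000L)[
      c("chrom", "intron_start", "intron_end", "strand")],
      random_junctions(25, chroms = "chr2L",
                       max_pos = 600L)[
        c("chrom", "intron_start", "intron_end", "strand")])
    asj <- find_as_junctions(jn)
    if (nrow(asj) == 0L) next
    st <- build_structures(asj, random_counts(asj, "s1"))
    ev <- classify_events(st, catalog = jn)
    for (e in ev) {
      if (e$pattern != "SE") next
      skip <- e$roles$skip
      ss <- as.integer(sub("^.*:(\\d+)-\\d+$", "\\1", skip))
      se_ <- as.integer(sub("^.*-(\\d+)$", "\\1", skip))
      expect_true(e$exon_coords[["exon_start"]] > ss)
      expect_true(e$exon_coords[["exon_end"]] < se_)
      expect_true(e$exon_coords[["exon_start"]] <=
                    e$exon_coords[["exon_end"]])
    }
  }
})

test_that("intron retention usage follows boundary evidence", {
  ev <- detect_intron_retention("chr2L:201-300",
                                junction_reads = c(90, 0, 0),
                                left = c(10, 0, 50), right = c(10, 0, 50))
  expect_equal(ev$pattern, "IR")
  expect_equal(unname(ev$retention_usage), c(0.1, NA, 1.0))
  expect_equal(unname(ev$fully_retained), c(FALSE, FALSE, TRUE))
  ev0 <- detect_intron_retention("chr2L:201-300", 90, 0, 0)
  expect_equal(unname(ev0$retention_usage), 0)
})

test_that("IR events are appended when boundary counts are supplied", {
  jn <- cassette_junctions()
  st <- build_structures(jn, random_counts(jn, "s1"))
  bc <- list(left = matrix(5, 1, 1, dimnames = list("chr2L:900-980", "s1")),
             right = matrix(7, 1, 1, dimnames = list("chr2L:900-980", "s1")),
             junction = matrix(54, 1, 1,
                               dimnames = list("chr2L:900-980", "s1")))
  ev <- classify_events(st, boundary_counts = bc)
  pats <- vapply(ev, `[[`, character(1), "pattern")
  expect_setequal(pats, c("SE", "IR"))
  ir <- ev[[which(pats == "IR")]]
  expect_equal(unname(ir$retention_usage), 6 / 60)
})
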