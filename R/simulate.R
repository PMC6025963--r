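# Synthetic splice-junction datasets with planted truth.
#
# The generator emulates the circadian-neuron time-course design: four
# neuron-like groups sampled every four hours across two days (6 timepoints
# x 2 replicate days = 12 samples per group), with cycling and
# non-cycling AS events of every pattern class, overdispersed counts
# (negative-binomial structure totals, Dirichlet-multinomial sub-junction
# splits) and a mix of annotated and novel junctions.

#' Simulation configuration
#'
#' All study conditions in one object. Defaults mirror the profiled
#' neuron time-course: groups DN1/LNd/LNv (circadian-like) and TH
#' (non-cycling control), 6 timepoints at 4 h spacing over 2 replicate
#' days, mean structure depth 100 reads per sample with negative-binomial
#' dispersion 0.15, Dirichlet-multinomial concentration 60 for the
#' sub-junction split, cycling amplitude 0.25 and planted usage difference
#' 0.30.
#'
#' @param events_per_pattern Named integer vector: number of planted events
#'   of each pattern (`SE`, `A5SS`, `A3SS`, `MXE`, `IR`, `Composite`).
#' @param background_genes Number of single-junction (non-AS) background
#'   genes, so support filters have something to remove.
#' @param conditions Sample group names; `control_condition` never cycles.
#' @param control_condition The non-cycling control group.
#' @param diff_pair Two conditions between which differential events are
#'   planted (default: first condition vs the control).
#' @param timepoints ZT hours of the sampling grid.
#' @param replicate_days Number of independent day series.
#' @param depth Mean structure junction reads per sample.
#' @param nb_dispersion Negative-binomial dispersion of structure totals
#'   (variance `mu + dispersion * mu^2`); 0 = deterministic totals.
#' @param concentration Dirichlet-multinomial concentration of the
#'   sub-junction split; `Inf` = exact multinomial-free split.
#' @param cycling_fraction Fraction of events planted as cycling.
#' @param cycling_amplitude Usage amplitude of cycling events, in
#'   `[0, 0.5)`.
#' @param phase_choices Peak phases sampled per cycling event x condition.
#' @param differential_fraction Fraction of events planted as differential
#'   between `diff_pair`.
#' @param delta_psi Planted usage difference of differential events.
#' @param novel_fraction Fraction of junctions withheld from the emitted
#'   annotation.
#' @param seed Integer seed; fully determines the dataset.
#' @return A `sim_config` list.
#' @export
sim_config <- function(events_per_pattern = c(SE = 5, A5SS = 5, A3SS = 5,
                                              MXE = 5, IR = 5,
                                              Composite = 5),
                       background_genes = 20,
                       conditions = c("DN1", "LNd", "LNv", "TH"),
                       control_condition = "TH",
                       diff_pair = NULL,
                       timepoints = seq(0, 20, by = 4),
                       replicate_days = 2,
                       depth = 100,
                       nb_dispersion = 0.15,
                       concentration = 60,
                       cycling_fraction = 0.2,
                       cycling_amplitude = 0.25,
                       phase_choices = seq(0, 20, by = 4),
                       differential_fraction = 0.2,
                       delta_psi = 0.3,
                       novel_fraction = 0.2,
                       seed = 1L) {
  if (cycling_amplitude < 0 || cycling_amplitude >= 0.5)
    stop("cycling_amplitude must lie in [0, 0.5)")
  if (!control_condition %in% conditions)
    stop("control_condition must be one of `conditions`")
  if (is.null(diff_pair))
    diff_pair <- c(conditions[1L], control_condition)
  if (!all(diff_pair %in% conditions) || length(diff_pair) != 2L)
    stop("diff_pair must name two of `conditions`")
  cfg <- list(events_per_pattern = events_per_pattern,
              background_genes = background_genes,
              conditions = conditions,
              control_condition = control_condition,
              diff_pair = diff_pair,
              timepoints = timepoints,
              replicate_days = replicate_days,
              depth = depth,
              nb_dispersion = nb_dispersion,
              concentration = concentration,
              cycling_fraction = cycling_fraction,
              cycling_amplitude = cycling_amplitude,
              phase_choices = phase_choices,
              differential_fraction = differential_fraction,
              delta_psi = delta_psi,
              novel_fraction = novel_fraction,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

.GENE_SPACING <- 10000L

# Junction geometry of one planted event, in gene-local coordinates.
# psi is the usage of the "alternative" role (inclusion / proximal /
# exon1 / retained).
.event_geometry <- function(pattern, strand) {
  j <- function(start, end, role, group)
    data.frame(start = start, end = end, role = role, group = group,
               stringsAsFactors = FALSE)
  switch(pattern,
    SE = rbind(j(201L, 300L, "inclusion-left", "alt"),
               j(401L, 500L, "inclusion-right", "alt"),
               j(201L, 500L, "skip", "other")),
    A3SS = if (strand == "+")
      rbind(j(201L, 400L, "proximal", "alt"),
            j(201L, 500L, "distal", "other"))
    else
      rbind(j(201L, 500L, "distal", "other"),
            j(301L, 500L, "proximal", "alt")),
    A5SS = if (strand == "+")
      rbind(j(201L, 500L, "distal", "other"),
            j(301L, 500L, "proximal", "alt"))
    else
      rbind(j(201L, 400L, "proximal", "alt"),
            j(201L, 500L, "distal", "other")),
    MXE = rbind(j(201L, 300L, "exon1-left", "alt"),
                j(201L, 500L, "exon2-left", "other"),
                j(401L, 700L, "exon1-right", "alt"),
                j(601L, 700L, "exon2-right", "other")),
    IR = j(201L, 300L, "retained-intron", "alt"),
    Composite = rbind(j(201L, 300L, "c1", "alt"),
                      j(201L, 400L, "c2", "other"),
                      j(201L, 500L, "c3", "other2")),
    background = j(201L, 300L, "constitutive", "alt"),
    stop("unknown pattern: ", pattern))
}

.gene_span <- function(pattern) {
  switch(pattern, MXE = 900L, 700L)
}

#' Simulate gene models, the junction catalog and the planted truth
#'
#' Lays out non-overlapping genes along one synthetic chromosome, one
#' planted AS event per gene (plus single-junction background genes),
#' instantiating the junction topology of each pattern. Each event draws a
#' base usage, cycling status (amplitude and a per-condition peak phase;
#' the control condition never cycles) and differential status (a usage
#' offset of `delta_psi` between the two `diff_pair` conditions). A
#' `novel_fraction` of junctions is withheld from the emitted annotation.
#' Cycling events are planted so that the true usage fold change across
#' the day exceeds the 1.5 detection gate (base usage within amplitude
#' bounds), i.e. planted cyclers are rhythmic under the operational
#' definition.
#'
#' @param config A [sim_config()].
#' @return A `sim_truth` list: `genes`, `junctions` (catalog with event
#'   membership, roles and novelty), `events` (pattern and gene per
#'   event), `trajectories` (per event x condition: base usage, amplitude,
#'   phase, differential delta) and the echoed `config`.
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  patterns <- rep(names(config$events_per_pattern),
                  config$events_per_pattern)
  patterns <- c(patterns, rep("background", config$background_genes))
  n_genes <- length(patterns)
  strands <- rep(c("+", "-"), length.out = n_genes)
  amp <- config$cycling_amplitude
  genes <- list(); juncs <- list(); events <- list(); traj <- list()
  offset <- 0L
  for (g in seq_len(n_genes)) {
    pattern <- patterns[g]
    strand <- strands[g]
    gene_id <- sprintf("g%03d", g)
    geo <- .event_geometry(pattern, strand)
    geo$start <- geo$start + offset
    geo$end <- geo$end + offset
    span <- .gene_span(pattern)
    genes[[g]] <- data.frame(gene_id = gene_id, chrom = "chrSim",
                             start = offset + 1L, end = offset + span,
                             strand = strand, stringsAsFactors = FALSE)
    is_event <- pattern != "background"
    event_id <- if (is_event) sprintf("ev%03d", g) else NA_character_
    if (is_event) {
      cycling <- stats::runif(1) < config$cycling_fraction
      differential <- stats::runif(1) < config$differential_fraction
      a <- if (cycling) amp else 0
      # base usage kept inside [0.01, 0.99] with the amplitude and the
      # differential offset; cycling bases also satisfy the >1.5 true
      # fold-change gate (base < 5 * amplitude or 1 - base < 5 * amplitude)
      lo <- max(0.15, a + 0.1)
      hi <- min(0.85, 1 - a - 0.1) - (if (differential) config$delta_psi
                                      else 0)
      if (hi <= lo) stop("infeasible usage bounds; lower delta_psi or ",
                         "cycling_amplitude")
      repeat {
        base <- stats::runif(1, lo, hi)
        if (!cycling || base < 5 * a || 1 - base < 5 * a) break
      }
      delta_dir <- 1  # planted offset raises usage in diff_pair[2]
      for (cond in config$conditions) {
        is_ctrl <- cond == config$control_condition
        traj[[length(traj) + 1L]] <- data.frame(
          event_id = event_id, condition = cond,
          base = base + (if (differential && cond == config$diff_pair[2L])
                           delta_dir * config$delta_psi else 0),
          amplitude = if (is_ctrl) 0 else a,
          phase = if (is_ctrl || !cycling) NA_real_ else
            sample(config$phase_choices, 1L),
          cycling = cycling && !is_ctrl,
          differential = differential && cond %in% config$diff_pair,
          stringsAsFactors = FALSE)
      }
      events[[length(events) + 1L]] <- data.frame(
        event_id = event_id, gene_id = gene_id, pattern = pattern,
        chrom = "chrSim", strand = strand, base_usage = base,
        cycling = cycling, differential = differential,
        stringsAsFactors = FALSE)
    }
    geo$gene_id <- gene_id
    geo$event_id <- event_id
    geo$chrom <- "chrSim"
    geo$strand <- strand
    geo$novel <- stats::runif(nrow(geo)) < config$novel_fraction
    juncs[[g]] <- geo
    offset <- offset + .GENE_SPACING
  }
  junctions <- do.call(rbind, juncs)
  junctions <- data.frame(chrom = junctions$chrom,
                          intron_start = junctions$start,
                          intron_end = junctions$end,
                          strand = junctions$strand,
                          gene_id = junctions$gene_id,
                          event_id = junctions$event_id,
                          role = junctions$role,
                          group = junctions$group,
                          novel = junctions$novel,
                          stringsAsFactors = FALSE)
  junctions$junction_id <- junction_id(junctions)
  out <- list(genes = do.call(rbind, genes),
              junctions = junctions,
              events = if (length(events)) do.call(rbind, events) else NULL,
              trajectories = if (length(traj)) do.call(rbind, traj)
                             else NULL,
              config = config)
  class(out) <- "sim_truth"
  out
}

.noise_free <- function(config) {
  config$nb_dispersion == 0 && !is.finite(config$concentration)
}

.draw_total <- function(config) {
  if (config$nb_dispersion == 0) return(as.integer(round(config$depth)))
  stats::rnbinom(1L, mu = config$depth, size = 1 / config$nb_dispersion)
}

.draw_split <- function(total, psi, config) {
  # returns count of the "alt" component
  if (.noise_free(config)) return(as.integer(round(total * psi)))
  p <- if (is.finite(config$concentration))
    stats::rbeta(1L, config$concentration * psi,
                 config$concentration * (1 - psi))
  else psi
  stats::rbinom(1L, total, p)
}

#' Simulate per-sample junction counts and boundary counts
#'
#' For every event and sample, the planted usage is
#' `psi(t) = base + amplitude * cos(2 * pi * (t - phase) / 24)` (clamped to
#' `[0.01, 0.99]`; differential events carry a condition-specific base).
#' Structure totals are negative-binomial around the configured depth, and
#' the sub-junction split is Dirichlet-multinomial (beta-binomial for
#' two-way events) around `psi`. Intron-retention boundary reads are
#' generated from the retention usage. The same seed yields identical
#' output.
#'
#' @param truth A `sim_truth` from [simulate_genome()].
#' @param config The same [sim_config()] (defaults to `truth$config`).
#' @return List with `counts` (junctions x samples integer matrix),
#'   `boundary` (list of `left`, `right`, `junction` matrices for IR
#'   junctions), `samples` (data frame: `sample`, `condition`, `day`,
#'   `timepoint`) and `junctions` (the catalog).
#' @export
simulate_counts <- function(truth, config = truth$config) {
  set.seed(as.integer((as.numeric(config$seed) + 1000003) %% 2147483647))
  samples <- expand.grid(timepoint = config$timepoints,
                         day = seq_len(config$replicate_days),
                         condition = config$conditions,
                         KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
  samples$sample <- sprintf("%s_day%d_ZT%02d", samples$condition,
                            samples$day, samples$timepoint)
  samples <- samples[, c("sample", "condition", "day", "timepoint")]
  jn <- truth$junctions
  counts <- matrix(0L, nrow(jn), nrow(samples),
                   dimnames = list(jn$junction_id, samples$sample))
  ir_ids <- jn$junction_id[!is.na(jn$event_id) & jn$role == "retained-intron"]
  boundary <- list(
    left = matrix(0L, length(ir_ids), nrow(samples),
                  dimnames = list(ir_ids, samples$sample)),
    right = matrix(0L, length(ir_ids), nrow(samples),
                   dimnames = list(ir_ids, samples$sample)),
    junction = matrix(0L, length(ir_ids), nrow(samples),
                      dimnames = list(ir_ids, samples$sample)))
  traj <- truth$trajectories
  traj_key <- if (!is.null(traj)) paste(traj$event_id, traj$condition)
  pattern_of <- if (!is.null(truth$events))
    stats::setNames(truth$events$pattern, truth$events$event_id)
  for (g in unique(jn$gene_id)) {
    rows <- jn[jn$gene_id == g, , drop = FALSE]
    ev <- rows$event_id[1L]
    pattern <- if (is.na(ev)) NA_character_ else pattern_of[[ev]]
    for (s in seq_len(nrow(samples))) {
      total <- .draw_total(config)
      if (is.na(ev)) {  # background: constitutive junction
        counts[rows$junction_id, s] <- total
        next
      }
      tr <- traj[match(paste(ev, samples$condition[s]), traj_key), ]
      psi <- tr$base
      if (tr$amplitude > 0 && !is.na(tr$phase))
        psi <- psi + tr$amplitude *
          cos(2 * pi * (samples$timepoint[s] - tr$phase) / 24)
      psi <- min(max(psi, 0.01), 0.99)
      if (pattern == "Composite") {
        # three-way split: alt component psi, remainder 60/40
        pvec <- c(psi, (1 - psi) * 0.6, (1 - psi) * 0.4)
        if (.noise_free(config)) {
          k <- as.integer(round(total * pvec))
        } else {
          if (is.finite(config$concentration)) {
            gam <- stats::rgamma(3L, shape = config$concentration * pvec)
            pvec <- gam / sum(gam)
          }
          k <- as.integer(stats::rmultinom(1L, total, pvec))
        }
        ord <- match(c("c1", "c2", "c3"), rows$role)
        counts[rows$junction_id[ord], s] <- k
      } else if (pattern == "IR") {
        retained <- .draw_split(total, psi, config)
        spliced <- total - retained
        counts[rows$junction_id, s] <- spliced
        boundary$left[rows$junction_id, s] <- retained
        boundary$right[rows$junction_id, s] <- retained
        boundary$junction[rows$junction_id, s] <- spliced
      } else {
        alt <- .draw_split(total, psi, config)
        other <- total - alt
        k <- ifelse(rows$group == "alt", alt,
                    ifelse(rows$group == "other", other,
                           NA_integer_))
        if (anyNA(k)) stop("unexpected junction group in event ", ev)
        counts[rows$junction_id, s] <- k
      }
    }
  }
  list(counts = counts, boundary = boundary, samples = samples,
       junctions = jn)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: [simulate_genome()] then [simulate_counts()].
#'
#' @param config A [sim_config()].
#' @return List with `truth`, `counts`, `boundary`, `samples`,
#'   `junctions`, `genes`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  truth <- simulate_genome(config)
  cnt <- simulate_counts(truth, config)
  list(truth = truth, counts = cnt$counts, boundary = cnt$boundary,
       samples = cnt$samples, junctions = truth$junctions,
       genes = truth$genes)
}

#' Write the planted truth tables
#'
#' Emits `truth_events.tsv`, `truth_junctions.tsv` and
#' `truth_trajectories.tsv` under `dir`; [read_truth()] restores them.
#'
#' @param truth A `sim_truth`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(truth$events, "truth_events.tsv")
  wt(truth$junctions, "truth_junctions.tsv")
  wt(truth$trajectories, "truth_trajectories.tsv")
  invisible(dir)
}

#' Read planted truth tables written by [write_truth()]
#'
#' @param dir Directory holding the truth TSVs.
#' @return List with `events`, `junctions`, `trajectories` data frames.
#' @export
read_truth <- function(dir) {
  rt <- function(f) utils::read.table(file.path(dir, f), sep = "\t",
                                      header = TRUE,
                                      stringsAsFactors = FALSE)
  list(events = rt("truth_events.tsv"),
       junctions = rt("truth_junctions.tsv"),
       trajectories = rt("truth_trajectories.tsv"))
}

#' Write a simulated dataset to disk
#'
#' Emits `annotation.gtf` (gene features plus a minimal two-exon
#' transcript per non-novel junction, so the annotated-junction library
#' equals the non-novel catalog), one STAR-dialect `SJ.out.tab` per sample
#' under `samples/`, `boundary_counts.tsv`, the truth tables and a JSON
#' echo of the configuration.
#'
#' @param sim A dataset from [simulate_dataset()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(file.path(dir, "samples"), showWarnings = FALSE,
             recursive = TRUE)
  writeLines(.sim_gtf_lines(sim$truth), file.path(dir, "annotation.gtf"))
  jn <- sim$junctions
  for (s in sim$samples$sample) {
    tab <- data.frame(chrom = jn$chrom,
                      intron_start = jn$intron_start,
                      intron_end = jn$intron_end,
                      strand = jn$strand,
                      motif = ifelse(jn$strand == "-", "CT/AC", "GT/AG"),
                      annotated = !jn$novel,
                      unique_reads = sim$counts[jn$junction_id, s],
                      multi_reads = 0L,
                      max_overhang = 30L,
                      stringsAsFactors = FALSE)
    write_sj_table(tab, file.path(dir, "samples",
                                  paste0(s, ".SJ.out.tab")))
  }
  b <- sim$boundary
  if (nrow(b$left)) {
    long <- do.call(rbind, lapply(rownames(b$left), function(j) {
      data.frame(junction_id = j, sample = colnames(b$left),
                 left = b$left[j, ], right = b$right[j, ],
                 junction = b$junction[j, ], stringsAsFactors = FALSE)
    }))
  } else {
    long <- data.frame(junction_id = character(), sample = character(),
                       left = integer(), right = integer(),
                       junction = integer())
  }
  utils::write.table(long, file.path(dir, "boundary_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_truth(sim$truth, dir)
  jsonlite::write_json(unclass(sim$truth$config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

.sim_gtf_lines <- function(truth) {
  lines <- character(0)
  attr_fmt <- 'gene_id "%s"; transcript_id "%s";'
  for (i in seq_len(nrow(truth$genes))) {
    g <- truth$genes[i, ]
    lines <- c(lines, sprintf(
      "%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
      g$chrom, g$start, g$end, g$strand, g$gene_id))
    jn <- truth$junctions[truth$junctions$gene_id == g$gene_id &
                            !truth$junctions$novel, , drop = FALSE]
    for (k in seq_len(nrow(jn))) {
      tx <- sprintf("%s.t%d", g$gene_id, k)
      a <- sprintf(attr_fmt, g$gene_id, tx)
      e1 <- c(jn$intron_start[k] - 50L, jn$intron_start[k] - 1L)
      e2 <- c(jn$intron_end[k] + 1L, jn$intron_end[k] + 50L)
      lines <- c(lines,
        sprintf("%s\tsim\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                g$chrom, e1[1L], e2[2L], g$strand, a),
        sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
                g$chrom, e1[1L], e1[2L], g$strand, a),
        sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
                g$chrom, e2[1L], e2[2L], g$strand, a))
    }
  }
  lines
}
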