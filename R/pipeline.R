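# End-to-end orchestration: junction IO -> AS structures -> pattern
# classification -> differential / cycling / summary analyses, with a JSON
# run manifest. Every threshold is a named configuration key defaulting to
# the published value (>10 reads, delta > 0.10, p <= 0.05, F24 > 0.5,
# fold > 1.5, JTK alpha 0.05).

.pipeline_defaults <- function() {
  list(min_reads = 10, delta_cutoff = 0.10, alpha = 0.05,
       f24_cutoff = 0.5, fold_cutoff = 1.5, jtk_alpha = 0.05,
       period = 24, analyses = c("differential", "cycling", "summarize"),
       seed = 1L)
}

.read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the yaml package")
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  utils::modifyList(.pipeline_defaults(), config)
}

#' Run the full junction-usage pipeline
#'
#' Reads per-sample splice-junction tables and the annotation, builds the
#' junction catalog and count matrix, identifies AS junctions and
#' structures, classifies patterns, and runs the requested analyses.
#' Re-running with identical inputs and seed reproduces identical result
#' tables.
#'
#' @param config A list (or path to a YAML/JSON file) with elements:
#'   `sj_tables` (named character vector of `SJ.out.tab` paths, names =
#'   samples), `annotation` (GTF path, optional), `sample_info` (data
#'   frame or TSV path with `sample`, `condition`, `day`, `timepoint`),
#'   `group_a`/`group_b` (sample names for the differential contrast),
#'   `boundary_counts` (TSV path, optional), `out_dir`, `analyses`
#'   (subset of `"differential"`, `"cycling"`, `"summarize"`), and the
#'   threshold keys `min_reads`, `delta_cutoff`, `alpha`, `f24_cutoff`,
#'   `fold_cutoff`, `jtk_alpha`, `period`, `seed`.
#' @return Invisibly, a list with the result tables (`structures`,
#'   `events`, and per-analysis outputs) and the run `manifest`; tables
#'   and the manifest are also written under `out_dir` when given.
#' @export
run_pipeline <- function(config) {
  cfg <- .read_pipeline_config(config)
  t0 <- Sys.time()
  if (is.null(cfg$sj_tables) || !length(cfg$sj_tables))
    stop("config must name input sj_tables")
  missing <- cfg$sj_tables[!file.exists(unlist(cfg$sj_tables))]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  set.seed(as.integer(cfg$seed))
  manifest <- list(config = cfg,
                   inputs = as.list(tools::md5sum(unlist(cfg$sj_tables))),
                   stages = list())
  log_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(..., elapsed_s = round(
      as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
    message(sprintf("[%s] %s", name,
                    paste(names(list(...)), unlist(list(...)),
                          sep = "=", collapse = " ")))
  }

  tables <- lapply(cfg$sj_tables, read_sj_table)
  catalog <- unique(do.call(rbind, lapply(tables, function(t)
    t[, c("chrom", "intron_start", "intron_end", "strand", "motif",
          "annotated")])))
  rownames(catalog) <- NULL
  jid <- junction_id(catalog)
  counts <- matrix(0L, nrow(catalog), length(tables),
                   dimnames = list(jid, names(tables)))
  for (s in names(tables)) {
    counts[junction_id(tables[[s]]), s] <- tables[[s]]$unique_reads
  }
  log_stage("junction_io", junctions_in = nrow(catalog),
            samples = length(tables))

  annotation <- NULL
  gene_asg <- NULL
  if (!is.null(cfg$annotation)) {
    annotation <- read_gtf_annotation(cfg$annotation)
    gene_asg <- assign_to_gene(catalog, annotation$genes)
    rownames(gene_asg) <- jid
  }

  asj <- find_as_junctions(catalog)
  structures <- build_structures(asj, counts)
  log_stage("as_structures", as_junctions = nrow(asj),
            non_as = nrow(catalog) - nrow(asj),
            structures = length(structures))

  boundary <- NULL
  if (!is.null(cfg$boundary_counts) && file.exists(cfg$boundary_counts)) {
    long <- utils::read.table(cfg$boundary_counts, sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
    ids <- unique(long$junction_id)
    mk <- function(col) {
      m <- matrix(0L, length(ids), ncol(counts),
                  dimnames = list(ids, colnames(counts)))
      m[cbind(match(long$junction_id, ids),
              match(long$sample, colnames(counts)))] <- long[[col]]
      m
    }
    boundary <- list(left = mk("left"), right = mk("right"),
                     junction = mk("junction"))
  }
  events <- classify_events(structures, boundary_counts = boundary,
                            catalog = catalog)
  ev_tab <- event_table(events, gene_asg)
  log_stage("pattern_classify", events = length(events))

  results <- list(structures = structure_table(structures),
                  events = ev_tab)

  sample_info <- cfg$sample_info
  if (is.character(sample_info))
    sample_info <- utils::read.table(sample_info, sep = "\t",
                                     header = TRUE,
                                     stringsAsFactors = FALSE)

  if ("differential" %in% cfg$analyses) {
    if (is.null(cfg$group_a) || is.null(cfg$group_b))
      stop("differential analysis requires group_a and group_b")
    results$differential <- run_differential(
      catalog, counts, cfg$group_a, cfg$group_b,
      min_reads = cfg$min_reads, delta_cutoff = cfg$delta_cutoff,
      alpha = cfg$alpha)
    log_stage("differential_as",
              tested = nrow(results$differential),
              significant = sum(results$differential$significant))
  }

  if ("cycling" %in% cfg$analyses) {
    if (is.null(sample_info))
      stop("cycling analysis requires sample_info (sample, day, timepoint)")
    conds <- unique(sample_info$condition %||% "all")
    cyc <- list()
    for (cond in conds) {
      si <- if (is.null(sample_info$condition)) sample_info else
        sample_info[sample_info$condition == cond, , drop = FALSE]
      r <- run_cycling(catalog, counts[, si$sample, drop = FALSE], si,
                       period = cfg$period, min_reads = cfg$min_reads,
                       f24_cutoff = cfg$f24_cutoff,
                       fold_cutoff = cfg$fold_cutoff,
                       jtk_alpha = cfg$jtk_alpha)
      if (nrow(r)) r$condition <- cond
      cyc[[cond]] <- r
    }
    results$cycling <- do.call(rbind, cyc)
    rownames(results$cycling) <- NULL
    log_stage("cycling", sub_junctions = nrow(results$cycling),
              cycling = sum(results$cycling$cycling))
  }

  if ("summarize" %in% cfg$analyses && !is.null(annotation)) {
    results$novelty <- classify_novelty(catalog, annotation,
                                        annotation$genes)
    log_stage("annotate_summarize",
              annotated = sum(results$novelty$status == "annotated"),
              novel = sum(results$novelty$status == "novel"),
              in_gene = sum(results$novelty$in_gene, na.rm = TRUE))
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    outputs <- character(0)
    for (nm in names(results)) {
      f <- file.path(cfg$out_dir, paste0(nm, ".tsv"))
      utils::write.table(results[[nm]], f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outputs <- c(outputs, f)
    }
    manifest$outputs <- outputs
    manifest$version <- as.character(utils::packageVersion("spliceclock"))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  results$manifest <- manifest
  invisible(results)
}
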