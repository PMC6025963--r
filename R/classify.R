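# Assembly of AS structures into canonical splicing patterns from
# splice-graph topology.
#
# Component graph: nodes are AS structures, with an edge whenever two
# structures share a junction. Patterns:
#   SE   - two structures (one start-, one end-anchored), two sub-junctions
#          each, sharing exactly one junction (the skip) whose span strictly
#          contains both inclusion junctions and a non-empty internal exon.
#   A5SS/A3SS - a lone two-junction structure; label resolved by anchor side
#          and strand.
#   MXE  - two lone two-junction structures (one start-, one end-anchored)
#          defining two disjoint candidate exons between a common flanking
#          donor and acceptor, with no junction in the catalog joining the
#          two exons. (The two structures of a pure mutually-exclusive pair
#          share no junction, so they appear as two components; an
#          exon-joining junction either merges the component, which is then
#          classified Composite, or is caught by the catalog scan.)
#   IR   - emitted per junction from exon-intron boundary read counts, in
#          addition to the junction-graph components.
#   Composite - everything else (the catch-all for inseparable combinations,
#          including structures with >= 3 sub-junctions).

#' Orient a lone two-junction structure as A5SS or A3SS
#'
#' A structure anchored at a shared intron start on the `+` strand (or a
#' shared intron end on the `-` strand) has a fixed donor and two
#' alternative acceptors: A3SS. The converse is A5SS. Junctions with
#' undefined strand cannot be oriented.
#'
#' @param structure An `as_structure`.
#' @param strand Optional strand override (`+`, `-`, `*`); defaults to the
#'   structure's consensus strand.
#' @return `"A3SS"`, `"A5SS"`, or `"A5SS/A3SS-unoriented"`.
#' @export
orient_a5ss_a3ss <- function(structure, strand = structure$strand) {
  if (!strand %in% c("+", "-")) return("A5SS/A3SS-unoriented")
  if ((structure$anchor_side == "start") == (strand == "+")) "A3SS"
  else "A5SS"
}

.new_event <- function(pattern, structures, roles, exon_coords = NULL,
                       extra = NULL) {
  chrom <- if (length(structures)) structures[[1L]]$chrom else
    extra$chrom
  strands <- unique(vapply(structures, function(s) s$strand, character(1)))
  strands <- setdiff(strands, "*")
  ev <- list(event_id = NA_character_,
             pattern = pattern,
             chrom = chrom,
             strand = if (length(strands) == 1L) strands else "*",
             structure_ids = vapply(structures, function(s) s$structure_id,
                                    character(1)),
             roles = roles,
             exon_coords = exon_coords)
  ev <- c(ev, extra)
  class(ev) <- "as_event"
  ev
}

.se_event <- function(sd, se) {
  # sd start-anchored at D1 with ends A1 < A2; se end-anchored at A2 with
  # starts D1 < D2; shared junction (D1, A2) is the skip.
  shared <- intersect(sd$junction_ids, se$junction_ids)
  if (length(shared) != 1L) return(NULL)
  skip_start <- sd$anchor_pos
  skip_end <- se$anchor_pos
  skip_id <- sprintf("%s:%d-%d", sd$chrom, skip_start, skip_end)
  if (shared != skip_id) return(NULL)
  incl_left <- setdiff(sd$junction_ids, shared)   # (D1, A1)
  incl_right <- setdiff(se$junction_ids, shared)  # (D2, A2)
  a1 <- sd$junctions$intron_end[sd$junction_ids == incl_left]
  d2 <- se$junctions$intron_start[se$junction_ids == incl_right]
  if (!(a1 < skip_end && d2 > skip_start)) return(NULL)  # nested in skip
  if (!(a1 + 1L <= d2 - 1L)) return(NULL)                # non-empty exon
  .new_event("SE", list(sd, se),
             roles = list(`inclusion-left` = incl_left,
                          `inclusion-right` = incl_right,
                          skip = shared),
             exon_coords = c(exon_start = a1 + 1L, exon_end = d2 - 1L))
}

.mxe_pair <- function(s_start, s_end, catalog) {
  # s_start anchored at donor D with ends a1 < a2; s_end anchored at
  # acceptor A with starts b1 < b2; candidate exons [a1+1, b1-1] and
  # [a2+1, b2-1] must be non-empty, disjoint and in order, with no junction
  # in the catalog joining exon 1 to exon 2.
  if (s_start$chrom != s_end$chrom) return(NULL)
  st <- c(s_start$strand, s_end$strand)
  st <- setdiff(unique(st), "*")
  if (length(st) > 1L) return(NULL)
  a <- s_start$junctions$intron_end    # sorted ascending
  b <- s_end$junctions$intron_start
  e1 <- c(a[1L] + 1L, b[1L] - 1L)
  e2 <- c(a[2L] + 1L, b[2L] - 1L)
  if (e1[1L] > e1[2L] || e2[1L] > e2[2L]) return(NULL)  # non-empty exons
  if (e1[2L] >= e2[1L]) return(NULL)                    # disjoint, ordered
  joining <- catalog$chrom == s_start$chrom &
    catalog$intron_start - 1L >= e1[1L] &
    catalog$intron_start - 1L <= e1[2L] &
    catalog$intron_end + 1L >= e2[1L] &
    catalog$intron_end + 1L <= e2[2L]
  if (any(joining)) return(NULL)
  .new_event("MXE", list(s_start, s_end),
             roles = list(`exon1-left` = s_start$junction_ids[1L],
                          `exon2-left` = s_start$junction_ids[2L],
                          `exon1-right` = s_end$junction_ids[1L],
                          `exon2-right` = s_end$junction_ids[2L]),
             exon_coords = rbind(exon1 = e1, exon2 = e2))
}

#' Classify AS structures into splicing-pattern events
#'
#' Builds the structure-sharing graph (structures linked by shared
#' junctions), takes connected components, and classifies each component as
#' SE, A5SS, A3SS, MXE or Composite by splice-graph topology (see Details
#' in the package vignette). Every input structure is assigned to exactly
#' one event. When boundary read counts are supplied, intron-retention
#' events are emitted in addition per junction with boundary evidence.
#'
#' @param structures List of `as_structure` objects.
#' @param boundary_counts Optional list with matrices `left` and `right`
#'   (junctions x samples) of reads spanning the exon-intron boundaries of
#'   each junction's intron, and `junction` (matching junction read counts;
#'   defaults to zero when absent).
#' @param catalog Optional full junction data frame used to veto
#'   mutually-exclusive-exon calls when a junction joins the two candidate
#'   exons; defaults to the union of the structures' junctions.
#' @return List of `as_event` objects with deterministic genomic-order ids.
#' @export
classify_events <- function(structures, boundary_counts = NULL,
                            catalog = NULL) {
  if (is.null(catalog) && length(structures))
    catalog <- unique(do.call(rbind, lapply(structures, `[[`, "junctions")))
  n <- length(structures)
  events <- list()
  if (n) {
    jids <- lapply(structures, `[[`, "junction_ids")
    memb <- data.frame(jid = unlist(jids),
                       str = rep(seq_len(n), lengths(jids)),
                       stringsAsFactors = FALSE)
    pairs <- do.call(rbind, lapply(split(memb$str, memb$jid), function(s) {
      if (length(s) < 2L) return(NULL)
      t(utils::combn(sort(s), 2L))
    }))
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (!is.null(pairs)) g <- igraph::add_edges(g, t(pairs))
    comp <- igraph::components(g)$membership

    lone <- integer(0)  # single two-junction structures, deferred
    for (cid in unique(comp)) {
      idx <- which(comp == cid)
      nsub <- vapply(structures[idx], function(s) length(s$junction_ids),
                     integer(1))
      if (length(idx) == 1L && nsub == 2L) {
        lone <- c(lone, idx)
        next
      }
      ev <- NULL
      if (length(idx) == 2L && all(nsub == 2L)) {
        sides <- vapply(structures[idx], `[[`, character(1), "anchor_side")
        if (setequal(sides, c("start", "end"))) {
          sd <- structures[[idx[sides == "start"]]]
          se <- structures[[idx[sides == "end"]]]
          ev <- .se_event(sd, se)
        }
      }
      if (is.null(ev)) {
        ev <- .new_event("Composite", structures[idx],
                         roles = stats::setNames(
                           as.list(unlist(jids[idx], use.names = FALSE)),
                           paste0("junction", seq_along(unlist(jids[idx])))))
      }
      events[[length(events) + 1L]] <- ev
    }

    # MXE pass over lone two-junction components, paired greedily in
    # genomic order; leftovers become A5SS/A3SS.
    if (length(lone)) {
      lone <- lone[order(vapply(structures[lone], `[[`, character(1),
                                "chrom"),
                         vapply(structures[lone], `[[`, numeric(1),
                                "anchor_pos"))]
      side_of <- vapply(structures[lone], `[[`, character(1), "anchor_side")
      used <- rep(FALSE, length(lone))
      for (i in seq_along(lone)) {
        if (used[i] || side_of[i] != "start") next
        for (j in seq_along(lone)) {
          if (used[j] || side_of[j] != "end") next
          ev <- .mxe_pair(structures[[lone[i]]], structures[[lone[j]]],
                          catalog)
          if (!is.null(ev)) {
            events[[length(events) + 1L]] <- ev
            used[c(i, j)] <- TRUE
            break
          }
        }
      }
      for (i in seq_along(lone)) {
        if (used[i]) next
        s <- structures[[lone[i]]]
        lab <- orient_a5ss_a3ss(s)
        events[[length(events) + 1L]] <- .new_event(
          lab, list(s),
          roles = list(proximal = s$junction_ids[1L],
                       distal = s$junction_ids[2L]))
      }
    }
  }

  if (!is.null(boundary_counts)) {
    ir <- detect_intron_retention_all(boundary_counts)
    events <- c(events, ir)
  }

  key <- vapply(events, function(e) {
    pos <- if (!is.null(e$anchor_pos)) e$anchor_pos else
      min(vapply(e$roles, function(r) .jid_start(r), numeric(1)))
    sprintf("%s:%012.0f:%s", e$chrom, pos, e$pattern)
  }, character(1))
  events <- events[order(key)]
  for (i in seq_along(events)) {
    events[[i]]$event_id <- sprintf("EV%05d", i)
  }
  events
}

.jid_start <- function(jid) {
  as.numeric(sub("^.*:(\\d+)-\\d+$", "\\1", jid))
}

#' @export
print.as_event <- function(x, ...) {
  cat(sprintf("AS event %s [%s] on %s(%s): %d structure(s)\n",
              x$event_id, x$pattern, x$chrom, x$strand,
              length(x$structure_ids)))
  invisible(x)
}

#' Detect intron retention from boundary read counts
#'
#' The spliced isoform is evidenced by junction-spanning reads, the
#' retained isoform by reads spanning the two exon-intron boundaries of the
#' junction's intron (averaged). Retained-isoform usage per sample is
#' `retained / (retained + junction)`; samples with no evidence of either
#' isoform are undefined.
#'
#' @param junction_id Junction identifier (`chrom:start-end`).
#' @param junction_reads Numeric vector of junction read counts per sample.
#' @param left,right Numeric vectors of boundary-spanning read counts per
#'   sample.
#' @return An `as_event` of pattern `"IR"` with per-sample
#'   `retention_usage` and a `fully_retained` flag (retention usage 1 with
#'   zero junction reads), or `NULL` when no sample has evidence.
#' @export
detect_intron_retention <- function(junction_id, junction_reads,
                                    left, right) {
  retained <- (left + right) / 2
  tot <- retained + junction_reads
  usage <- ifelse(tot > 0, retained / tot, NA_real_)
  chrom <- sub(":.*$", "", junction_id)
  ev <- .new_event("IR", list(),
                   roles = list(spliced = junction_id),
                   extra = list(chrom = chrom,
                                retention_usage = usage,
                                fully_retained = !is.na(usage) &
                                  usage == 1 & junction_reads == 0))
  ev$strand <- "*"
  ev
}

detect_intron_retention_all <- function(boundary_counts) {
  left <- as.matrix(boundary_counts$left)
  right <- as.matrix(boundary_counts$right)
  jr <- boundary_counts$junction
  if (is.null(jr)) jr <- left * 0 else jr <- as.matrix(jr)
  jids <- rownames(left)
  lapply(jids, function(j) {
    detect_intron_retention(j, jr[j, ], left[j, ], right[j, ])
  })
}

#' Tabulate classified AS events
#'
#' @param events List of `as_event` objects from [classify_events()].
#' @param gene_assignment Optional data frame from [assign_to_gene()] with
#'   rownames equal to junction ids, used to attach a gene id per event.
#' @return Data frame with one row per event: id, pattern, chromosome,
#'   strand, member structures, defining junction roles and inferred
#'   alternative exon coordinates (where applicable).
#' @export
event_table <- function(events, gene_assignment = NULL) {
  rows <- lapply(events, function(e) {
    roles <- paste(sprintf("%s=%s", names(e$roles), unlist(e$roles)),
                   collapse = ";")
    exons <- if (is.null(e$exon_coords)) NA_character_ else
      paste(apply(rbind(e$exon_coords), 1L,
                  function(x) sprintf("%d-%d", x[1L], x[2L])),
            collapse = ";")
    gene <- NA_character_
    if (!is.null(gene_assignment)) {
      j <- unlist(e$roles)[1L]
      if (j %in% rownames(gene_assignment))
        gene <- gene_assignment[j, "gene_id"]
    }
    data.frame(event_id = e$event_id, pattern = e$pattern,
               chrom = e$chrom, strand = e$strand,
               gene_id = gene,
               n_structures = length(e$structure_ids),
               structure_ids = paste(e$structure_ids, collapse = ";"),
               junction_roles = roles, exon_coords = exons,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
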