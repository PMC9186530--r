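# End-to-end assembly pipeline: compress -> mask -> correct -> exact
# overlaps -> string graph -> simplify -> multiplicity -> walks (with
# optional ultra-long read arbitration) -> run-length consensus.

#' Assemble a genome from simulated long reads
#'
#' Runs the full desk-scale pipeline on accurate (HiFi-like) reads, with
#' optional noisy ultra-long (ONT-like) reads used to arbitrate ambiguous
#' repeat tangles. Each connected component of the simplified string graph
#' is resolved independently.
#'
#' @param hifi_reads data.frame with `id`, `bases` (uncompressed).
#' @param ont_reads optional data.frame of ultra-long reads.
#' @param min_overlap minimum exact overlap in compressed bases; default
#'   40% of the median compressed read length (long enough that
#'   diff-free windows across diverged repeat copies are rare).
#' @param correction_rounds number of correction passes (default 1).
#' @param min_identity,band,k,w see [all_pairs_align()].
#' @param tip_len,bubble_len see [simplify_graph()].
#' @param min_margin see [select_walk()].
#' @param max_candidates see [enumerate_candidates()].
#' @param anchor_k see [align_ont_to_graph()].
#' @param verbose print stage progress.
#' @return list with `assembly` (data.frame `id`, `bases`, `status`),
#'   `graph` (simplified, multiplicity-annotated `string_graph`), `walks`
#'   (list of chosen walks per component), `issues` (low-coverage issue
#'   table) and `n_components`.
#' @export
assemble <- function(hifi_reads, ont_reads = NULL, min_overlap = NULL,
                     correction_rounds = 1L, min_identity = 0.98,
                     band = 12L, k = 21L, w = 50L, tip_len = NULL,
                     bubble_len = 500L, min_margin = 2,
                     max_candidates = 10000L, anchor_k = 17L,
                     verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("compressing %d reads", nrow(hifi_reads))
  hpc <- hpc_compress_set(hifi_reads)
  bridge_ids <- character(0)
  med_len <- median(nchar(hpc$bases))
  if (is.null(min_overlap)) min_overlap <- max(500L, as.integer(0.4 * med_len))
  if (is.null(tip_len)) tip_len <- as.integer(1.6 * med_len)
  for (round in seq_len(correction_rounds)) {
    say("correction round %d: masking", round)
    masks <- mask_reads(hpc)
    say("correction round %d: all-vs-all alignment", round)
    aln <- all_pairs_align(hpc, min_overlap = min_overlap,
                           min_identity = min_identity, k = k, w = w,
                           band = band)
    say("correction round %d: correcting (%d alignments)", round, nrow(aln))
    hpc <- correct_reads(hpc, aln, masks, band = band)
  }
  say("exact overlaps")
  masks <- mask_reads(hpc)
  ovl <- exact_overlaps(hpc, masks, min_overlap = min_overlap, k = k, w = w)
  say("building graph (%d overlaps)", nrow(ovl))
  g <- build_graph(hpc, ovl)
  g <- estimate_multiplicity(g)
  # purge reads whose only placement is on below-noise (artifact) nodes:
  # reads carrying residual errors otherwise act as low-depth bridges that
  # absorb the true overlaps during transitive reduction
  bad_nodes <- g$nodes$id[!is.na(g$nodes$multiplicity) &
                            g$nodes$multiplicity == 0L]
  if (length(bad_nodes) > 0) {
    on_bad <- g$placements$read_id[g$placements$node %in% bad_nodes]
    on_good <- g$placements$read_id[!(g$placements$node %in% bad_nodes)]
    drop_ids <- setdiff(on_bad, on_good)
    if (length(drop_ids) > 0) {
      g2 <- build_graph(hpc_subset(hpc, !(hpc$id %in% drop_ids)),
                        ovl[!(ovl$from %in% drop_ids) &
                              !(ovl$to %in% drop_ids), , drop = FALSE])
      # a purged read whose partners now sit in different components is a
      # genuine junction bridge (the only read spanning it), not an
      # artifact: keep it
      comp2 <- graph_components(g2)
      read_comp <- setNames(comp2[match(g2$placements$node, g2$nodes$id)],
                            g2$placements$read_id)
      bridges <- vapply(drop_ids, function(rid) {
        rows <- ovl[ovl$from == rid | ovl$to == rid, , drop = FALSE]
        partners <- setdiff(unique(c(rows$from, rows$to)), rid)
        cc <- unique(read_comp[partners])
        length(cc[!is.na(cc)]) >= 2
      }, logical(1))
      bridge_ids <- drop_ids[bridges]
      drop_ids <- drop_ids[!bridges]
      say("purging %d artifact reads (%d junction bridges kept), rebuilding",
          length(drop_ids), length(bridge_ids))
      if (length(drop_ids) > 0) {
        keep <- !(hpc$id %in% drop_ids)
        hpc <- hpc_subset(hpc, keep)
        ovl <- ovl[!(ovl$from %in% drop_ids) & !(ovl$to %in% drop_ids), ,
                   drop = FALSE]
        g <- build_graph(hpc, ovl)
        g <- estimate_multiplicity(g)
      }
    }
  }
  say("simplifying (%d nodes)", nrow(g$nodes))
  g <- simplify_graph(g, tip_len = tip_len, bubble_len = bubble_len)
  g <- estimate_multiplicity(g)
  if (length(bridge_ids) > 0) {
    # a kept junction bridge is traversed once even though its depth is
    # below the noise threshold
    bn <- unique(g$placements$node[g$placements$read_id %in% bridge_ids])
    bi <- match(bn, g$nodes$id)
    bi <- bi[!is.na(bi)]
    bi <- bi[g$nodes$multiplicity[bi] == 0L]
    g$nodes$multiplicity[bi] <- 1L
  }
  comp <- graph_components(g)
  say("%d nodes in %d components", nrow(g$nodes), length(unique(comp)))
  galn <- if (!is.null(ont_reads) && nrow(g$nodes) > 0) {
    say("aligning %d ultra-long reads to graph", nrow(ont_reads))
    align_ont_to_graph(ont_reads, g, anchor_k = anchor_k)
  } else list()
  assembly <- list(); walks <- list(); issues <- list()
  for (cp in sort(unique(comp))) {
    cn <- g$nodes$id[comp == cp]
    # skip pure-artifact components
    mlt <- g$nodes$multiplicity[comp == cp]
    if (all(!is.na(mlt) & mlt == 0L)) next
    cands <- enumerate_candidates(g, cn, max_candidates = max_candidates)
    if (length(cands) == 0) next
    sel <- select_walk(cands, galn, g, min_margin = min_margin)
    for (wi in seq_along(sel)) {
      wk <- sel[[wi]]
      wk$id <- sprintf("contig%03d_%d", cp, wi)
      cons <- walk_consensus(wk, g, hpc)
      assembly[[length(assembly) + 1L]] <- data.frame(
        id = wk$id, bases = cons$bases, status = wk$status,
        stringsAsFactors = FALSE)
      walks[[length(walks) + 1L]] <- wk
      if (nrow(cons$issues) > 0) {
        cons$issues$target <- wk$id
        issues[[length(issues) + 1L]] <- cons$issues
      }
    }
  }
  list(assembly = do.call(rbind, assembly) %||%
         data.frame(id = character(0), bases = character(0),
                    status = character(0)),
       graph = g, walks = walks,
       issues = do.call(rbind, issues) %||%
         data.frame(target = character(0), start = integer(0),
                    end = integer(0), kind = character(0),
                    evidence = character(0)),
       n_components = length(unique(comp)))
}

#' Percent identity between two sequences
#'
#' Banded global edit distance (band widened to cover the length
#' difference), reported as a percentage of the longer sequence; the better
#' of the forward and reverse-complement orientations of `b` is returned.
#'
#' @param a,b DNA strings.
#' @param band alignment band half-width (default 200).
#' @return identity in percent (0-100).
#' @export
seq_identity <- function(a, b, band = 200L) {
  if (nchar(a) == 0 || nchar(b) == 0) return(0)
  d1 <- cpp_banded_edit(a, b, as.integer(band))
  d2 <- cpp_banded_edit(a, revcomp(b), as.integer(band))
  100 * (1 - min(d1, d2) / max(nchar(a), nchar(b)))
}
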