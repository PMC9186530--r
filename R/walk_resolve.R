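# Repeat/tangle resolution: enumerate candidate chromosome walks through
# the string graph under the node-multiplicity constraints, arbitrate
# between them with ultra-long read-to-graph alignments, and compute an
# uncompressed run-length consensus for the chosen walks.

walk_signature <- function(steps) paste(steps$node, steps$orient, collapse = " ")

rc_steps <- function(steps) {
  data.frame(node = rev(steps$node),
             orient = ifelse(rev(steps$orient) == "+", "-", "+"),
             stringsAsFactors = FALSE)
}

canon_walk <- function(steps) {
  s1 <- walk_signature(steps)
  s2 <- walk_signature(rc_steps(steps))
  if (s2 < s1) rc_steps(steps) else steps
}

#' Enumerate candidate walks through a graph component
#'
#' Finds all ways (up to `max_candidates`) to cover the component with
#' walks that traverse each multiplicity-m node exactly m times and each
#' multiplicity-0 node not at all. Walks start at free node ends and are
#' extended while any extension remains; a candidate is a *set* of walks
#' (one chromosome arm each), since a component may legitimately carry
#' several chromosomes that share repeat nodes. Candidates are
#' deduplicated up to walk orientation and order.
#'
#' @param graph a `string_graph` with multiplicities set (see
#'   [estimate_multiplicity()]; NA multiplicities count as 1).
#' @param nodes optional character vector of node ids restricting the
#'   search to one component (default: all nodes).
#' @param max_candidates cap on enumerated candidates; beyond it the
#'   result is flagged ambiguous (honesty over sampling).
#' @param max_steps cap on search steps.
#' @return list of candidates; each candidate is a list of walks, each walk
#'   a list with `id`, `steps` (data.frame `node`, `orient`) and `status`
#'   ("resolved" if the candidate is unique, else "ambiguous").
#'   Attribute `truncated` reports whether either cap was hit.
#' @export
enumerate_candidates <- function(graph, nodes = NULL,
                                 max_candidates = 10000L,
                                 max_steps = 200000L) {
  ids <- nodes %||% graph$nodes$id
  idx <- match(ids, graph$nodes$id)
  mult <- graph$nodes$multiplicity[idx]
  mult[is.na(mult)] <- 1L
  nidx <- setNames(seq_along(ids), ids)
  ve <- graph_vertex_edges(graph)
  gidx <- setNames(seq_len(nrow(graph$nodes)), graph$nodes$id)
  # restrict and relabel vertex edges to the subset
  if (nrow(ve) > 0) {
    keep <- graph$nodes$id[vread(ve$u)] %in% ids &
      graph$nodes$id[vread(ve$w)] %in% ids
    ve <- ve[keep, , drop = FALSE]
    ve$u <- vid(nidx[graph$nodes$id[vread(ve$u)]], vorient(ve$u))
    ve$w <- vid(nidx[graph$nodes$id[vread(ve$w)]], vorient(ve$w))
    # multiplicity-0 (artifact) nodes are never traversed; drop their edges
    ve <- ve[mult[vread(ve$u)] > 0L & mult[vread(ve$w)] > 0L, , drop = FALSE]
  }
  n <- length(ids)
  out <- vector("list", 2L * n)
  if (nrow(ve) > 0) {
    sp <- split(ve$w, ve$u)
    for (k in names(sp)) out[[as.integer(k)]] <- sp[[k]]
  }
  indeg0 <- vapply(seq_len(2L * n), function(v)
    !any(ve$w == v), logical(1))
  env <- new.env(parent = emptyenv())
  env$found <- list()
  env$keys <- character(0)
  env$steps <- 0L
  env$truncated <- FALSE
  emit <- function(walks) {
    walks <- lapply(walks, canon_walk)
    key <- paste(sort(vapply(walks, walk_signature, character(1))),
                 collapse = " | ")
    if (!(key %in% env$keys)) {
      env$keys <- c(env$keys, key)
      env$found[[length(env$found) + 1L]] <- walks
    }
  }
  vsteps <- function(vs) data.frame(node = ids[vread(vs)],
                                    orient = vorient(vs),
                                    stringsAsFactors = FALSE)
  rec <- function(counts, walks, cur) {
    if (env$truncated) return()
    env$steps <- env$steps + 1L
    if (env$steps > max_steps || length(env$found) >= max_candidates) {
      env$truncated <- TRUE
      return()
    }
    if (is.null(cur)) {
      if (all(counts == 0L)) {
        emit(walks)
        return()
      }
      starts <- which(indeg0 & counts[vread(seq_len(2L * n))] > 0L)
      if (length(starts) == 0L) {
        # circular remainder: fix a canonical entry point
        starts <- min(which(counts[vread(seq_len(2L * n))] > 0L))
      }
      for (s in starts) {
        c2 <- counts
        c2[vread(s)] <- c2[vread(s)] - 1L
        rec(c2, walks, s)
      }
    } else {
      v <- cur[length(cur)]
      nb <- out[[v]]
      nb <- nb[counts[vread(nb)] > 0L]
      if (length(nb) == 0L) {
        rec(counts, c(walks, list(vsteps(cur))), NULL)
      } else {
        for (w in unique(nb)) {
          c2 <- counts
          c2[vread(w)] <- c2[vread(w)] - 1L
          rec(c2, walks, c(cur, w))
        }
      }
    }
  }
  rec(mult, list(), NULL)
  cands <- env$found
  # parsimony: each walk is one chromosome (arm); candidates that split
  # the component into more walks than necessary are artifacts of early
  # walk termination, not alternative structures
  if (length(cands) > 1L) {
    nw <- vapply(cands, length, integer(1))
    cands <- cands[nw == min(nw)]
  }
  status <- if (length(cands) == 1L && !env$truncated) "resolved" else "ambiguous"
  cands <- lapply(seq_along(cands), function(i) {
    lapply(seq_along(cands[[i]]), function(j)
      list(id = sprintf("cand%d_walk%d", i, j), steps = cands[[i]][[j]],
           status = status))
  })
  attr(cands, "truncated") <- env$truncated
  cands
}

#' Align ultra-long reads to the string graph
#'
#' Unique-anchor seeding (k-mers occurring exactly once across all node
#' sequences) followed by adjacency-constrained chaining: anchors are
#' ordered along the read, collapsed into oriented node visits, and the
#' resulting path is kept only if every consecutive node pair is joined by
#' a graph edge. Reads with no confident path are omitted (counted in the
#' `n_omitted` attribute).
#'
#' @param ont_reads data.frame with `id`, `bases` (uncompressed; they are
#'   homopolymer-compressed internally to match the graph's space).
#' @param graph a `string_graph`.
#' @param anchor_k anchor k-mer size in compressed space (default 17).
#' @param w anchor sampling rate (default 5).
#' @param min_anchors minimum anchors per node visit (default 3).
#' @param compress whether to homopolymer-compress reads first (default
#'   TRUE; set FALSE if reads are already in compressed space).
#' @return list of graph alignments: each a list with `read_id`, `path`
#'   (data.frame `node`, `orient`), `n_anchors`, `span` (compressed bases
#'   between first and last anchor).
#' @export
align_ont_to_graph <- function(ont_reads, graph, anchor_k = 17L, w = 5L,
                               min_anchors = 3L, compress = TRUE) {
  # Edge overlaps mean the same genomic sequence is present in two node
  # chains; index each overlap region on one node only (the shorter node
  # keeps it, so short repeat cores remain anchorable).
  lens <- graph$nodes$len
  omask <- lapply(lens, function(l) NULL)
  ve0 <- graph_vertex_edges(graph)
  if (nrow(ve0) > 0) {
    seen <- character(0)
    for (r in seq_len(nrow(ve0))) {
      u <- ve0$u[r]; wv <- ve0$w[r]; L <- ve0$L[r]
      key <- paste(min(u, wv), max(u, wv), L)
      if (key %in% seen) next # complement of an already-handled edge
      seen <- c(seen, key)
      nu <- vread(u); nw <- vread(wv)
      if (lens[nu] >= lens[nw]) {
        # mask u's side: last L of u's oriented sequence
        iv <- if (vorient(u) == "+") c(lens[nu] - L, lens[nu]) else c(0L, L)
        omask[[nu]] <- rbind(omask[[nu]], data.frame(start = iv[1], end = iv[2]))
      } else {
        # mask w's side: first L of w's oriented sequence
        iv <- if (vorient(wv) == "+") c(0L, L) else c(lens[nw] - L, lens[nw])
        omask[[nw]] <- rbind(omask[[nw]], data.frame(start = iv[1], end = iv[2]))
      }
    }
  }
  nseeds <- data.table::rbindlist(lapply(seq_len(nrow(graph$nodes)), function(i) {
    df <- cpp_kmer_scan(graph$nodes$bases[i], as.integer(anchor_k), as.integer(w))
    if (nrow(df) == 0) return(NULL)
    if (!is.null(omask[[i]])) {
      mv <- intervals_to_mask(omask[[i]], lens[i])
      keep <- !mv[df$pos + 1L] &
        !mv[pmin(lens[i], df$pos + as.integer(anchor_k))]
      df <- df[keep, , drop = FALSE]
      if (nrow(df) == 0) return(NULL)
    }
    data.table::data.table(node = i, npos = df$pos, code = df$code,
                           nfwd = df$fwd)
  }))
  if (is.null(nseeds) || nrow(nseeds) == 0) {
    out <- list()
    attr(out, "n_omitted") <- nrow(ont_reads)
    return(out)
  }
  occ <- nseeds[, list(nocc = .N), by = "code"]
  nseeds <- merge(nseeds, occ[occ$nocc == 1L, "code"], by = "code")
  data.table::setkey(nseeds, code)
  ve <- graph_vertex_edges(graph)
  edge_keys <- paste(ve$u, ve$w)
  res <- list()
  omitted <- 0L
  for (r in seq_len(nrow(ont_reads))) {
    bases <- if (compress) hpc_compress(ont_reads$bases[r])$bases
             else ont_reads$bases[r]
    rs <- cpp_kmer_scan(bases, as.integer(anchor_k), as.integer(w))
    if (nrow(rs) == 0) { omitted <- omitted + 1L; next }
    rdt <- data.table::data.table(code = rs$code, rpos = rs$pos, rfwd = rs$fwd)
    m <- merge(rdt, nseeds, by = "code")
    if (nrow(m) < min_anchors) { omitted <- omitted + 1L; next }
    data.table::setorder(m, rpos)
    orient <- ifelse(m$rfwd == m$nfwd, "+", "-")
    runs <- rle(paste(m$node, orient))
    step_end <- cumsum(runs$lengths)
    step_start <- step_end - runs$lengths + 1L
    keep <- runs$lengths >= min_anchors
    if (!any(keep)) { omitted <- omitted + 1L; next }
    st <- data.frame(node = m$node[step_start], orient = orient[step_start],
                     anchors = runs$lengths, stringsAsFactors = FALSE)[keep, , drop = FALSE]
    # collapse repeats created by dropping noise steps
    if (nrow(st) > 1) {
      same <- c(FALSE, st$node[-1] == st$node[-nrow(st)] &
                  st$orient[-1] == st$orient[-nrow(st)])
      st$grp <- cumsum(!same)
      agg <- lapply(split(seq_len(nrow(st)), st$grp), function(ii)
        data.frame(node = st$node[ii[1]], orient = st$orient[ii[1]],
                   anchors = sum(st$anchors[ii]), stringsAsFactors = FALSE))
      st <- do.call(rbind, agg)
    }
    # adjacency check
    ok <- TRUE
    if (nrow(st) > 1) {
      for (i in seq_len(nrow(st) - 1L)) {
        u <- vid(st$node[i], st$orient[i])
        wv <- vid(st$node[i + 1L], st$orient[i + 1L])
        if (!(paste(u, wv) %in% edge_keys)) { ok <- FALSE; break }
      }
    }
    if (!ok) { omitted <- omitted + 1L; next }
    res[[length(res) + 1L]] <- list(
      read_id = ont_reads$id[r],
      path = data.frame(node = graph$nodes$id[st$node], orient = st$orient,
                        stringsAsFactors = FALSE),
      n_anchors = sum(st$anchors),
      span = max(m$rpos) - min(m$rpos))
  }
  attr(res, "n_omitted") <- omitted
  res
}

# does `path` occur as a contiguous subpath of `walk` (either strand)?
is_subpath <- function(path, walk_steps) {
  pat1 <- paste0(" ", walk_signature(path), " ")
  pat2 <- paste0(" ", walk_signature(rc_steps(path)), " ")
  hay <- paste0(" ", walk_signature(walk_steps), " ")
  grepl(pat1, hay, fixed = TRUE) || grepl(pat2, hay, fixed = TRUE)
}

#' Select the best-supported candidate walk set
#'
#' A graph alignment supports a candidate iff its node path is a contiguous
#' subpath of one of the candidate's walks (either strand) and includes at
#' least one full traversal of a repeat node (multiplicity >= 2, interior
#' to the read path: the read both enters and leaves the repeat). The
#' winner must have at least `min_margin` times the runner-up's support;
#' otherwise the result is flagged ambiguous. A single candidate is
#' resolved without evidence.
#'
#' @param candidates output of [enumerate_candidates()].
#' @param alignments output of [align_ont_to_graph()] (may be empty).
#' @param graph the `string_graph` (for multiplicities).
#' @param min_margin winner/runner-up support ratio (default 2).
#' @return the chosen candidate (list of walks) with each walk's `status`
#'   set to "resolved" or "ambiguous"; attributes `support` (per-candidate
#'   counts) and `status`.
#' @export
select_walk <- function(candidates, alignments, graph, min_margin = 2) {
  stopifnot(length(candidates) >= 1)
  if (length(candidates) == 1L && !isTRUE(attr(candidates, "truncated"))) {
    cand <- candidates[[1]]
    cand <- lapply(cand, function(w) { w$status <- "resolved"; w })
    attr(cand, "support") <- NA_integer_
    attr(cand, "status") <- "resolved"
    return(cand)
  }
  multi <- Filter(function(al) nrow(al$path) >= 2, alignments)
  if (length(multi) == 0) {
    support <- rep(0L, length(candidates))
  } else {
    # support matrix: read x candidate subpath membership
    supmat <- vapply(candidates, function(cand) {
      vapply(multi, function(al)
        any(vapply(cand, function(wk) is_subpath(al$path, wk$steps),
                   logical(1))), logical(1))
    }, logical(length(multi)))
    supmat <- matrix(supmat, nrow = length(multi))
    # only discriminating reads count: paths consistent with every candidate
    # (e.g. a partial repeat entry) carry no evidence either way
    disc <- rowSums(supmat) > 0 & rowSums(supmat) < length(candidates)
    support <- colSums(supmat[disc, , drop = FALSE])
  }
  ord <- order(support, decreasing = TRUE)
  winner <- ord[1]
  runner <- if (length(ord) > 1) support[ord[2]] else 0L
  resolved <- support[winner] >= 1L &&
    support[winner] >= min_margin * max(runner, 1L) &&
    !(runner == support[winner])
  status <- if (resolved && !isTRUE(attr(candidates, "truncated")))
    "resolved" else "ambiguous"
  cand <- lapply(candidates[[winner]], function(w) { w$status <- status; w })
  attr(cand, "support") <- support
  attr(cand, "status") <- status
  cand
}

#' Write walks as a GAF-like TSV
#'
#' One row per walk: id, status, and the oriented node list in
#' `>node`/`<node` notation.
#'
#' @param walks list of walks (as from [select_walk()]).
#' @param path output path.
#' @export
write_walks <- function(walks, path) {
  rows <- vapply(walks, function(w) {
    steps <- paste0(ifelse(w$steps$orient == "+", ">", "<"), w$steps$node,
                    collapse = "")
    paste(w$id %||% "walk", w$status %||% "NA", steps, sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

# modal run length per node position (smaller run wins ties); returns
# integer vector of length node_len, with attribute "uncovered" marking
# positions with no read support (run length 1 there)
node_modal_runs <- function(graph, hpc, node_id) {
  i <- match(node_id, graph$nodes$id)
  len <- graph$nodes$len[i]
  pl <- graph$placements[graph$placements$node == node_id, , drop = FALSE]
  runs_out <- rep(1L, len)
  uncovered <- rep(TRUE, len)
  if (nrow(pl) == 0) {
    attr(runs_out, "uncovered") <- uncovered
    return(runs_out)
  }
  ri <- match(pl$read_id, hpc$id)
  pos_all <- vector("list", nrow(pl))
  run_all <- vector("list", nrow(pl))
  for (j in seq_len(nrow(pl))) {
    m <- pl$read_len[j]
    if (is.na(ri[j])) next
    p <- pl$offset[j] + 0:(m - 1L)
    q <- if (pl$orient[j] == "+") 0:(m - 1L) else (m - 1L):0
    inb <- p >= 0L & p < len
    pos_all[[j]] <- p[inb]
    run_all[[j]] <- hpc$runs[[ri[j]]][q + 1L][inb]
  }
  dt <- data.table::data.table(pos = unlist(pos_all), run = unlist(run_all))
  if (nrow(dt) == 0) {
    attr(runs_out, "uncovered") <- uncovered
    return(runs_out)
  }
  cnt <- dt[, list(n = .N), by = c("pos", "run")]
  data.table::setorder(cnt, pos, -n, run)
  best <- cnt[!duplicated(cnt$pos), ]
  runs_out[best$pos + 1L] <- best$run
  uncovered[best$pos + 1L] <- FALSE
  attr(runs_out, "uncovered") <- uncovered
  runs_out
}

#' Run-length consensus of a walk
#'
#' Lays out the walk's compressed backbone (trimming edge overlaps between
#' consecutive nodes) and sets each compressed position's run length to the
#' modal run length among the accurate reads placed at that position, with
#' ties broken toward the smaller run. Positions with no read support emit
#' the compressed base with run length 1 and are recorded as low-coverage
#' issues.
#'
#' @param walk a walk (list with `steps`, as produced by
#'   [enumerate_candidates()]/[select_walk()]).
#' @param graph the `string_graph` with read placements.
#' @param hpc the corrected `hpc_set` whose run lengths came from the
#'   original (uncompressed) reads.
#' @return list with `id`, `bases` (uncompressed consensus), `issues`
#'   (data.frame of low-coverage intervals on the consensus, compressed
#'   coordinates).
#' @export
walk_consensus <- function(walk, graph, hpc) {
  steps <- walk$steps
  ve <- graph_vertex_edges(graph)
  idx <- setNames(seq_len(nrow(graph$nodes)), graph$nodes$id)
  run_cache <- new.env(parent = emptyenv())
  get_runs <- function(nid) {
    if (is.null(run_cache[[nid]])) run_cache[[nid]] <- node_modal_runs(graph, hpc, nid)
    run_cache[[nid]]
  }
  chars <- character(0)
  runs <- integer(0)
  uncov <- logical(0)
  for (i in seq_len(nrow(steps))) {
    nid <- steps$node[i]
    ni <- idx[nid]
    bases <- graph$nodes$bases[ni]
    rl <- get_runs(nid)
    uc <- attr(rl, "uncovered")
    if (steps$orient[i] == "-") {
      bases <- revcomp(bases)
      rl <- rev(rl)
      uc <- rev(uc)
    }
    ch <- strsplit(bases, "", fixed = TRUE)[[1]]
    trim <- 0L
    if (i > 1L) {
      u <- vid(idx[steps$node[i - 1L]], steps$orient[i - 1L])
      w <- vid(ni, steps$orient[i])
      hit <- ve$u == u & ve$w == w
      trim <- if (any(hit)) max(ve$L[hit]) else 0L
    }
    if (trim > 0L && trim < length(ch)) {
      ch <- ch[-seq_len(trim)]
      rl <- rl[-seq_len(trim)]
      uc <- uc[-seq_len(trim)]
    } else if (trim >= length(ch)) {
      next # node fully swallowed by the overlap
    }
    chars <- c(chars, ch)
    runs <- c(runs, rl)
    uncov <- c(uncov, uc)
  }
  issues <- NULL
  if (any(uncov)) {
    r <- rle(uncov)
    e <- cumsum(r$lengths)
    s <- e - r$lengths
    issues <- data.frame(target = walk$id %||% "walk",
                         start = s[r$values], end = e[r$values],
                         kind = "low_coverage",
                         evidence = "no read support for run length",
                         stringsAsFactors = FALSE)
  }
  issues <- issues %||% data.frame(target = character(0), start = integer(0),
                                   end = integer(0), kind = character(0),
                                   evidence = character(0))
  list(id = walk$id %||% "walk",
       bases = paste(strrep(chars, runs), collapse = ""),
       issues = issues)
}
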