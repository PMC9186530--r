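# Bidirected string graph: construction from exact overlaps, unitigging,
# iterative simplification (transitive reduction, tip clipping, bubble
# popping), node depth/multiplicity annotation, and GFA1 serialisation.
#
# Internal representation: each element (read, later unitig) i has two
# vertices, 2i-1 (forward, "+") and 2i (reverse, "-"). A directed edge
# u -> w of length L means "the suffix of u's oriented sequence equals the
# prefix of w's oriented sequence over L compressed bases"; every edge has
# a complement flip(w) -> flip(u). This node-end adjacency realises the
# bidirected graph.

vid <- function(i, orient) ifelse(orient == "+", 2L * i - 1L, 2L * i)
vread <- function(v) (v + 1L) %/% 2L
vorient <- function(v) ifelse(v %% 2L == 1L, "+", "-")
vflip <- function(v) ifelse(v %% 2L == 1L, v + 1L, v - 1L)

# expand overlap rows (dovetails only) into the directed vertex edge table,
# complements included, deduplicated keeping max overlap length
overlap_edges <- function(overlaps, id2idx) {
  dv <- overlaps[is.na(overlaps$contained), , drop = FALSE]
  if (nrow(dv) == 0)
    return(data.frame(u = integer(0), w = integer(0), L = integer(0)))
  fi <- id2idx[dv$from]
  ti <- id2idx[dv$to]
  u <- vid(fi, dv$from_orient)
  w <- vid(ti, dv$to_orient)
  e <- data.frame(u = c(u, vflip(w)), w = c(w, vflip(u)), L = c(dv$len, dv$len))
  e <- e[order(e$u, e$w, -e$L), ]
  e[!duplicated(e[, c("u", "w")]), , drop = FALSE]
}

# Myers-style transitive reduction with fuzz on the extension lengths.
# edges: data.frame(u, w, L); elen: element lengths (indexed by element).
# Returns the reduced edge table (symmetric: an edge and its complement are
# removed together).
reduce_transitive <- function(edges, elen, fuzz = 10L) {
  if (nrow(edges) == 0) return(edges)
  ext <- elen[vread(edges$w)] - edges$L # new sequence each edge adds
  key <- paste(edges$u, edges$w)
  ext_by_key <- setNames(ext, key)
  out_by_u <- split(seq_len(nrow(edges)), edges$u)
  drop <- logical(nrow(edges))
  for (u in names(out_by_u)) {
    ei <- out_by_u[[u]]
    if (length(ei) < 2) next
    targets <- edges$w[ei]
    exts <- ext[ei]
    for (j in seq_along(ei)) {
      wv <- targets[j]
      wi <- out_by_u[[as.character(wv)]]
      if (is.null(wi)) next
      hit <- match(edges$w[wi], targets)
      ok <- which(!is.na(hit) & edges$w[wi] != wv)
      for (h in ok) {
        tot <- exts[j] + ext[wi[h]]
        direct <- exts[hit[h]]
        if (abs(tot - direct) <= fuzz) drop[ei[hit[h]]] <- TRUE
      }
    }
  }
  # symmetrise: drop complements of dropped edges too
  comp_key <- paste(vflip(edges$w), vflip(edges$u))
  cdrop <- drop[match(comp_key, key)]
  cdrop[is.na(cdrop)] <- FALSE
  edges[!(drop | cdrop), , drop = FALSE]
}

# collapse maximal unambiguous chains of elements into merged items.
# edges: directed vertex edges (complements present). lens: element lengths.
# Returns list(chains = list of list(elems, orients, offsets, total_len,
# internal_L), edges = data.frame(from_chain, from_orient, to_chain,
# to_orient, L) with complements deduplicated).
collapse_chains <- function(n_elem, lens, edges) {
  outdeg <- integer(2L * n_elem)
  indeg <- integer(2L * n_elem)
  if (nrow(edges) > 0) {
    tu <- table(edges$u); ti <- table(edges$w)
    outdeg[as.integer(names(tu))] <- as.integer(tu)
    indeg[as.integer(names(ti))] <- as.integer(ti)
  }
  nxt <- integer(2L * n_elem)
  nxtL <- integer(2L * n_elem)
  if (nrow(edges) > 0) {
    uniq <- edges[outdeg[edges$u] == 1L & indeg[edges$w] == 1L, , drop = FALSE]
    nxt[uniq$u] <- uniq$w
    nxtL[uniq$u] <- uniq$L
  }
  prv <- integer(2L * n_elem)
  prv[nxt[nxt > 0]] <- which(nxt > 0)
  used <- logical(n_elem)
  chains <- list()
  elem_chain <- integer(n_elem)       # which chain holds each element
  build_from <- function(v0) {
    vs <- integer(0)
    Ls <- integer(0)
    v <- v0
    repeat {
      if (used[vread(v)]) break
      vs <- c(vs, v)
      used[vread(v)] <<- TRUE
      w <- nxt[v]
      if (w == 0L) break
      Ls <- c(Ls, nxtL[v])
      v <- w
    }
    if (length(Ls) >= length(vs)) Ls <- Ls[seq_len(max(0L, length(vs) - 1L))]
    list(vs = vs, Ls = Ls)
  }
  starts <- which(vapply(seq_len(2L * n_elem), function(v)
    prv[v] == 0L, logical(1)))
  for (v0 in starts) {
    if (used[vread(v0)]) next
    ch <- build_from(v0)
    if (length(ch$vs) == 0) next
    elems <- vread(ch$vs)
    orients <- vorient(ch$vs)
    offs <- c(0L, cumsum(lens[elems[-length(elems)]] - ch$Ls))
    chains[[length(chains) + 1L]] <- list(
      elems = elems, orients = orients, offsets = offs,
      total_len = offs[length(offs)] + lens[elems[length(elems)]],
      internal_L = ch$Ls)
    elem_chain[elems] <- length(chains)
  }
  # leftover cycles
  for (i in which(!used)) {
    if (used[i]) next
    ch <- build_from(vid(i, "+"))
    if (length(ch$vs) == 0) next
    elems <- vread(ch$vs)
    orients <- vorient(ch$vs)
    offs <- c(0L, cumsum(lens[elems[-length(elems)]] - ch$Ls))
    chains[[length(chains) + 1L]] <- list(
      elems = elems, orients = orients, offsets = offs,
      total_len = offs[length(offs)] + lens[elems[length(elems)]],
      internal_L = ch$Ls)
    elem_chain[elems] <- length(chains)
  }
  # map chain-end vertices to oriented chains
  first_v <- vapply(chains, function(c) vid(c$elems[1], c$orients[1]), integer(1))
  last_v <- vapply(chains, function(c)
    vid(c$elems[length(c$elems)], c$orients[length(c$elems)]), integer(1))
  # remaining (non-internal) edges become chain-level edges
  chain_edges <- NULL
  if (nrow(edges) > 0) {
    internal <- nxt[edges$u] == edges$w
    rem <- edges[!internal, , drop = FALSE]
    if (nrow(rem) > 0) {
      from_chain <- integer(nrow(rem)); from_or <- character(nrow(rem))
      to_chain <- integer(nrow(rem)); to_or <- character(nrow(rem))
      ok <- logical(nrow(rem))
      for (r in seq_len(nrow(rem))) {
        u <- rem$u[r]; w <- rem$w[r]
        cu <- elem_chain[vread(u)]; cw <- elem_chain[vread(w)]
        if (cu == 0L || cw == 0L) next
        if (u == last_v[cu]) { from_chain[r] <- cu; from_or[r] <- "+" }
        else if (u == vflip(first_v[cu])) { from_chain[r] <- cu; from_or[r] <- "-" }
        else next
        if (w == first_v[cw]) { to_chain[r] <- cw; to_or[r] <- "+" }
        else if (w == vflip(last_v[cw])) { to_chain[r] <- cw; to_or[r] <- "-" }
        else next
        ok[r] <- TRUE
      }
      if (any(ok)) {
        chain_edges <- data.frame(from_chain = from_chain[ok],
                                  from_orient = from_or[ok],
                                  to_chain = to_chain[ok], to_orient = to_or[ok],
                                  L = rem$L[ok], stringsAsFactors = FALSE)
        # dedupe complements: keep canonical representative
        keyf <- paste(chain_edges$from_chain, chain_edges$from_orient,
                      chain_edges$to_chain, chain_edges$to_orient)
        flip <- function(o) ifelse(o == "+", "-", "+")
        keyc <- paste(chain_edges$to_chain, flip(chain_edges$to_orient),
                      chain_edges$from_chain, flip(chain_edges$from_orient))
        chain_edges <- chain_edges[keyf <= keyc |
                                     !(keyc %in% keyf), , drop = FALSE]
        chain_edges <- chain_edges[!duplicated(paste(
          chain_edges$from_chain, chain_edges$from_orient,
          chain_edges$to_chain, chain_edges$to_orient)), , drop = FALSE]
      }
    }
  }
  if (is.null(chain_edges))
    chain_edges <- data.frame(from_chain = integer(0), from_orient = character(0),
                              to_chain = integer(0), to_orient = character(0),
                              L = integer(0), stringsAsFactors = FALSE)
  list(chains = chains, edges = chain_edges)
}

# splice oriented element sequences along a chain into one string
splice_chain <- function(chain, seqs_fwd, seqs_rev) {
  parts <- character(length(chain$elems))
  for (i in seq_along(chain$elems)) {
    s <- if (chain$orients[i] == "+") seqs_fwd[chain$elems[i]]
         else seqs_rev[chain$elems[i]]
    if (i == 1L) parts[i] <- s
    else {
      L <- chain$internal_L[i - 1L]
      parts[i] <- substr(s, L + 1L, nchar(s))
    }
  }
  paste(parts, collapse = "")
}

#' Build the bidirected string graph from exact overlaps
#'
#' Contained reads are excluded from graph construction but placed back on
#' their containers for depth computation. Transitive edges are removed
#' (Myers reduction) and maximal unambiguous paths are merged into unitig
#' nodes, recording the layout of every constituent read.
#'
#' @param hpc corrected `hpc_set` of compressed reads.
#' @param overlaps exact overlap table from [exact_overlaps()].
#' @param fuzz transitive-reduction length tolerance (compressed bases).
#' @return object of class `string_graph`: list with `nodes` (data.frame
#'   `id`, `bases`, `len`, `support`, `depth`, `multiplicity`), `edges`
#'   (data.frame `from`, `from_orient`, `to`, `to_orient`, `len`; one row
#'   per bidirected edge, complement implicit) and `placements` (data.frame
#'   `node`, `read_id`, `offset`, `orient`, `read_len`).
#' @export
build_graph <- function(hpc, overlaps, fuzz = 10L) {
  n <- length(hpc$id)
  id2idx <- setNames(seq_len(n), hpc$id)
  if (nrow(overlaps) > 0 &&
      (any(is.na(id2idx[overlaps$from])) || any(is.na(id2idx[overlaps$to]))))
    stop("overlap references unknown read")
  lens <- nchar(hpc$bases)
  cont_rows <- overlaps[!is.na(overlaps$contained), , drop = FALSE]
  contained <- unique(id2idx[cont_rows$contained])
  dove <- overlaps[is.na(overlaps$contained), , drop = FALSE]
  if (length(contained) > 0 && nrow(dove) > 0) {
    dove <- dove[!(id2idx[dove$from] %in% contained) &
                   !(id2idx[dove$to] %in% contained), , drop = FALSE]
  }
  edges <- overlap_edges(dove, id2idx)
  edges <- reduce_transitive(edges, lens, fuzz)
  cc <- collapse_chains(n, lens, edges)
  # drop chains made solely of contained reads (they have no vertices when
  # contained reads were excluded from edges; they still appear as
  # singletons, so filter explicitly)
  keep <- vapply(cc$chains, function(ch)
    !all(ch$elems %in% contained), logical(1))
  chain_ids <- cumsum(keep)
  rc_bases <- revcomp(hpc$bases)
  nodes <- list(); placements <- list()
  for (ci in seq_along(cc$chains)) {
    if (!keep[ci]) next
    ch <- cc$chains[[ci]]
    nid <- sprintf("utg%06d", chain_ids[ci])
    bases <- splice_chain(ch, hpc$bases, rc_bases)
    placements[[length(placements) + 1L]] <- data.frame(
      node = nid, read_id = hpc$id[ch$elems], offset = ch$offsets,
      orient = ch$orients, read_len = lens[ch$elems],
      stringsAsFactors = FALSE)
    nodes[[length(nodes) + 1L]] <- data.frame(
      id = nid, bases = bases, len = nchar(bases),
      support = length(ch$elems), depth = 0, multiplicity = NA_integer_,
      stringsAsFactors = FALSE)
  }
  nodes <- do.call(rbind, nodes) %||%
    data.frame(id = character(0), bases = character(0), len = integer(0),
               support = integer(0), depth = numeric(0),
               multiplicity = integer(0))
  placements <- do.call(rbind, placements) %||%
    data.frame(node = character(0), read_id = character(0),
               offset = integer(0), orient = character(0),
               read_len = integer(0))
  # place contained reads onto their containers (possibly nested)
  if (length(contained) > 0) {
    cont_map <- cont_rows[!duplicated(cont_rows$contained), , drop = FALSE]
    place_one <- function(rid) {
      # returns (container_id, start, end, orient) with a non-contained
      # container, or NULL
      row <- cont_map[cont_map$contained == rid, , drop = FALSE]
      if (nrow(row) == 0) return(NULL)
      cs <- row$from_start; ce <- row$from_end; ro <- row$strand
      cid <- row$from
      guard <- 0L
      while (cid %in% cont_map$contained && guard < 50L) {
        guard <- guard + 1L
        up <- cont_map[cont_map$contained == cid, , drop = FALSE]
        lc <- lens[id2idx[cid]]
        if (up$strand == "+") {
          cs <- up$from_start + cs; ce <- up$from_start + ce
        } else {
          tmp <- cs
          cs <- up$from_start + (lc - ce)
          ce <- up$from_start + (lc - tmp)
          ro <- ifelse(ro == "+", "-", "+")
        }
        cid <- up$from
      }
      list(cid = cid, cs = cs, ce = ce, ro = ro)
    }
    extra <- list()
    for (rid in hpc$id[contained]) {
      pl <- place_one(rid)
      if (is.null(pl)) next
      host <- placements[placements$read_id == pl$cid, , drop = FALSE]
      if (nrow(host) == 0) next
      host <- host[1, ]
      if (host$orient == "+") {
        off <- host$offset + pl$cs; orient <- pl$ro
      } else {
        off <- host$offset + (host$read_len - pl$ce)
        orient <- ifelse(pl$ro == "+", "-", "+")
      }
      extra[[length(extra) + 1L]] <- data.frame(
        node = host$node, read_id = rid, offset = off, orient = orient,
        read_len = lens[id2idx[rid]], stringsAsFactors = FALSE)
    }
    if (length(extra) > 0) placements <- rbind(placements, do.call(rbind, extra))
  }
  # depth: reads per compressed base
  if (nrow(nodes) > 0) {
    agg <- tapply(placements$read_len, placements$node, sum)
    nodes$depth <- as.numeric(agg[nodes$id] / nodes$len)
    nodes$depth[is.na(nodes$depth)] <- 0
  }
  # chain-level edges -> node ids
  ce <- cc$edges
  old2new <- setNames(sprintf("utg%06d", chain_ids), seq_along(cc$chains))
  ce <- ce[keep[ce$from_chain] & keep[ce$to_chain], , drop = FALSE]
  edges_df <- data.frame(from = old2new[as.character(ce$from_chain)],
                         from_orient = ce$from_orient,
                         to = old2new[as.character(ce$to_chain)],
                         to_orient = ce$to_orient, len = ce$L,
                         stringsAsFactors = FALSE)
  rownames(nodes) <- rownames(placements) <- rownames(edges_df) <- NULL
  structure(list(nodes = nodes, edges = edges_df, placements = placements),
            class = "string_graph")
}

# expand the stored (canonical) bidirected edges into both directed
# representatives, as a data.frame(u, w, L) over node indices
graph_vertex_edges <- function(graph) {
  idx <- setNames(seq_len(nrow(graph$nodes)), graph$nodes$id)
  e <- graph$edges
  if (nrow(e) == 0) return(data.frame(u = integer(0), w = integer(0), L = integer(0)))
  u <- vid(idx[e$from], e$from_orient)
  w <- vid(idx[e$to], e$to_orient)
  out <- data.frame(u = c(u, vflip(w)), w = c(w, vflip(u)), L = c(e$len, e$len))
  out <- out[!duplicated(out[, c("u", "w")]), , drop = FALSE]
  out
}

# rebuild a string_graph from node subsets / chain collapse after edits
rebuild_graph <- function(graph, vedges) {
  n <- nrow(graph$nodes)
  lens <- graph$nodes$len
  cc <- collapse_chains(n, lens, vedges)
  rc_bases <- revcomp(graph$nodes$bases)
  nodes <- list(); placements <- list()
  for (ci in seq_along(cc$chains)) {
    ch <- cc$chains[[ci]]
    nid <- sprintf("utg%06d", ci)
    bases <- splice_chain(ch, graph$nodes$bases, rc_bases)
    dep <- sum(graph$nodes$depth[ch$elems] * lens[ch$elems]) / nchar(bases)
    nodes[[ci]] <- data.frame(id = nid, bases = bases, len = nchar(bases),
                              support = sum(graph$nodes$support[ch$elems]),
                              depth = dep, multiplicity = NA_integer_,
                              stringsAsFactors = FALSE)
    # shift placements of constituent nodes
    for (i in seq_along(ch$elems)) {
      old <- graph$nodes$id[ch$elems[i]]
      pl <- graph$placements[graph$placements$node == old, , drop = FALSE]
      if (nrow(pl) == 0) next
      if (ch$orients[i] == "+") {
        pl$offset <- pl$offset + ch$offsets[i]
      } else {
        pl$offset <- ch$offsets[i] +
          (lens[ch$elems[i]] - (pl$offset + pl$read_len))
        pl$orient <- ifelse(pl$orient == "+", "-", "+")
      }
      pl$node <- nid
      placements[[length(placements) + 1L]] <- pl
    }
  }
  nodes <- do.call(rbind, nodes) %||% graph$nodes[0, ]
  placements <- do.call(rbind, placements) %||% graph$placements[0, ]
  if (nrow(placements) > 0 && nrow(nodes) > 0) {
    # depth from actual read placements where available
    agg <- tapply(placements$read_len, placements$node, sum)
    has <- nodes$id %in% names(agg)
    nodes$depth[has] <- as.numeric(agg[nodes$id[has]]) / nodes$len[has]
  }
  ce <- cc$edges
  edges_df <- data.frame(from = sprintf("utg%06d", ce$from_chain),
                         from_orient = ce$from_orient,
                         to = sprintf("utg%06d", ce$to_chain),
                         to_orient = ce$to_orient, len = ce$L,
                         stringsAsFactors = FALSE)
  rownames(nodes) <- rownames(placements) <- rownames(edges_df) <- NULL
  structure(list(nodes = nodes, edges = edges_df, placements = placements),
            class = "string_graph")
}

#' Iteratively simplify a string graph
#'
#' Per iteration: transitive edge reduction, tip clipping (dead-end nodes
#' shorter than `tip_len` with depth below `tip_depth_frac` times the graph
#' median depth), small-bubble popping (two parallel single-node paths of
#' length at most `bubble_len` between the same node ends; the higher-depth
#' path is retained), then re-merging of unambiguous chains. Stops early at
#' convergence; idempotent once converged.
#'
#' @param graph a `string_graph`.
#' @param tip_len maximum length of a clippable tip (compressed bases,
#'   default 1000 at desk scale).
#' @param bubble_len maximum branch length of a poppable bubble (default
#'   500).
#' @param iterations iteration cap (default 10).
#' @param tip_depth_frac depth threshold for tips, as a fraction of the
#'   median node depth (default 0.5).
#' @param fuzz transitive-reduction tolerance.
#' @return the simplified `string_graph`.
#' @export
simplify_graph <- function(graph, tip_len = 1000L, bubble_len = 500L,
                           iterations = 10L, tip_depth_frac = 0.5,
                           fuzz = 10L) {
  for (it in seq_len(iterations)) {
    n0 <- nrow(graph$nodes); e0 <- nrow(graph$edges)
    ve <- graph_vertex_edges(graph)
    ve <- reduce_transitive(ve, graph$nodes$len, fuzz)
    base <- median(graph$nodes$depth[graph$nodes$len > 0])
    drop_node <- logical(nrow(graph$nodes))
    outdeg <- integer(2L * nrow(graph$nodes))
    if (nrow(ve) > 0) {
      tu <- table(ve$u)
      outdeg[as.integer(names(tu))] <- as.integer(tu)
    }
    # tips: one free end, short, low depth, and attached at the other end
    for (i in seq_len(nrow(graph$nodes))) {
      vp <- vid(i, "+"); vm <- vid(i, "-")
      din <- outdeg[vm] # out-edges of reverse == in-edges of forward
      dout <- outdeg[vp]
      free_end <- xor(dout == 0L, din == 0L)
      if (free_end && graph$nodes$len[i] < tip_len &&
          graph$nodes$depth[i] < tip_depth_frac * base)
        drop_node[i] <- TRUE
    }
    # bubbles: v -> {n1, n2} -> w with n1, n2 simple
    if (nrow(ve) > 0) {
      outs <- split(seq_len(nrow(ve)), ve$u)
      ins <- split(seq_len(nrow(ve)), ve$w)
      deg_in <- function(v) length(ins[[as.character(v)]] %||% integer(0))
      deg_out <- function(v) length(outs[[as.character(v)]] %||% integer(0))
      for (u in names(outs)) {
        ei <- outs[[u]]
        if (length(ei) < 2) next
        tg <- ve$w[ei]
        simple <- vapply(tg, function(v) {
          i <- vread(v)
          !drop_node[i] && deg_in(v) == 1L && deg_out(v) == 1L
        }, logical(1))
        if (sum(simple) < 2) next
        nxt_of <- vapply(tg, function(v) {
          o <- outs[[as.character(v)]]
          if (is.null(o) || length(o) != 1L) NA_integer_ else ve$w[o]
        }, integer(1))
        cand <- which(simple & !is.na(nxt_of))
        if (length(cand) < 2) next
        for (dest in unique(nxt_of[cand])) {
          members <- cand[nxt_of[cand] == dest]
          if (length(members) < 2) next
          nodes_i <- vread(tg[members])
          if (any(graph$nodes$len[nodes_i] > bubble_len)) next
          keep_i <- nodes_i[which.max(graph$nodes$depth[nodes_i])]
          drop_node[setdiff(nodes_i, keep_i)] <- TRUE
        }
      }
    }
    if (any(drop_node)) {
      bad <- which(drop_node)
      ve <- ve[!(vread(ve$u) %in% bad) & !(vread(ve$w) %in% bad), , drop = FALSE]
      # relabel by subsetting: rebuild with dropped nodes as isolated, then filter
      keep_ids <- graph$nodes$id[!drop_node]
      g2 <- rebuild_graph(graph_subset(graph, bad), remap_vedges(ve, bad))
      graph <- g2
    } else {
      graph <- rebuild_graph(graph, ve)
    }
    if (nrow(graph$nodes) == n0 && nrow(graph$edges) == e0) break
  }
  graph
}

# drop nodes by index, keeping the rest (edges filtered separately)
graph_subset <- function(graph, drop_idx) {
  keep <- setdiff(seq_len(nrow(graph$nodes)), drop_idx)
  ids <- graph$nodes$id[keep]
  structure(list(nodes = graph$nodes[keep, , drop = FALSE],
                 edges = graph$edges[graph$edges$from %in% ids &
                                       graph$edges$to %in% ids, , drop = FALSE],
                 placements = graph$placements[
                   graph$placements$node %in% ids, , drop = FALSE]),
            class = "string_graph")
}

# remap vertex edges after dropping node indices
remap_vedges <- function(ve, drop_idx) {
  n_old <- max(c(vread(ve$u), vread(ve$w), drop_idx, 0L))
  keep <- setdiff(seq_len(n_old), drop_idx)
  new_idx <- integer(n_old)
  new_idx[keep] <- seq_along(keep)
  ve$u <- vid(new_idx[vread(ve$u)], vorient(ve$u))
  ve$w <- vid(new_idx[vread(ve$w)], vorient(ve$w))
  ve
}

#' Estimate node multiplicities from depth
#'
#' Multiplicity is the inferred number of times a node's sequence occurs in
#' the genome: round(depth / base_depth), floored at 1 for nodes above the
#' noise threshold and 0 (candidate artifact) below it.
#'
#' @param graph a `string_graph`.
#' @param base_depth haploid base depth; if NULL, the median depth of nodes
#'   longer than the 90th length percentile (robust to repeat inflation).
#' @param noise_frac nodes with depth below `noise_frac * base_depth` get
#'   multiplicity 0 (default 0.2).
#' @param refine_flow when TRUE (default), refine the depth-based estimate
#'   by flow consistency: if every in-neighbor of a node end is forced to
#'   enter it (out-degree 1), the node must be visited at least the sum of
#'   their multiplicities. This corrects repeat cores whose depth is
#'   diluted because repeat-spanning reads are absorbed by the flanking
#'   nodes (their chains extend into the repeat).
#' @return the graph with `nodes$multiplicity` set.
#' @export
estimate_multiplicity <- function(graph, base_depth = NULL, noise_frac = 0.2,
                                  refine_flow = is.null(base_depth)) {
  if (nrow(graph$nodes) == 0) return(graph)
  force(refine_flow)
  if (is.null(base_depth)) {
    q <- quantile(graph$nodes$len, 0.9, names = FALSE)
    base_depth <- median(graph$nodes$depth[graph$nodes$len >= q])
  }
  if (is.na(base_depth) || base_depth <= 0) stop("base_depth must be > 0")
  m <- round(graph$nodes$depth / base_depth)
  m[graph$nodes$depth < noise_frac * base_depth] <- 0L
  m[m < 1L & graph$nodes$depth >= noise_frac * base_depth] <- 1L
  m <- as.integer(m)
  if (refine_flow && nrow(graph$edges) > 0) {
    ve <- graph_vertex_edges(graph)
    outdeg <- integer(2L * nrow(graph$nodes))
    tu <- table(ve$u)
    outdeg[as.integer(names(tu))] <- as.integer(tu)
    ins <- split(ve$u, ve$w)
    for (sweep in 1:3) {
      for (v in names(ins)) {
        vi <- as.integer(v)
        ni <- vread(vi)
        if (m[ni] == 0L) next
        srcs <- ins[[v]]
        if (all(outdeg[srcs] == 1L)) {
          forced <- sum(m[vread(srcs)])
          if (forced > m[ni]) m[ni] <- forced
        }
      }
    }
  }
  graph$nodes$multiplicity <- m
  graph
}

#' Connected components of a string graph
#'
#' @param graph a `string_graph`.
#' @return integer vector of component labels, one per node.
#' @export
graph_components <- function(graph) {
  n <- nrow(graph$nodes)
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  if (nrow(graph$edges) > 0) {
    idx <- setNames(seq_len(n), graph$nodes$id)
    for (r in seq_len(nrow(graph$edges))) {
      a <- find(idx[graph$edges$from[r]]); b <- find(idx[graph$edges$to[r]])
      if (a != b) comp[max(a, b)] <- min(a, b)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Export a string graph as GFA1
#'
#' S lines carry `dp:f:` (depth), `ml:i:` (multiplicity) and `rd:i:`
#' (read support) tags; L lines encode the bidirected edges with the
#' overlap length as a CIGAR match.
#'
#' @param graph a `string_graph`.
#' @param path output path.
#' @export
export_gfa <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  for (i in seq_len(nrow(graph$nodes))) {
    nd <- graph$nodes[i, ]
    ml <- if (is.na(nd$multiplicity)) "" else sprintf("\tml:i:%d", nd$multiplicity)
    writeLines(sprintf("S\t%s\t%s\tdp:f:%.4f\trd:i:%d%s",
                       nd$id, nd$bases, nd$depth, nd$support, ml), con)
  }
  for (i in seq_len(nrow(graph$edges))) {
    e <- graph$edges[i, ]
    writeLines(sprintf("L\t%s\t%s\t%s\t%s\t%dM",
                       e$from, e$from_orient, e$to, e$to_orient, e$len), con)
  }
  invisible(path)
}

#' Import a GFA1 string graph
#'
#' Round trip with [export_gfa()] preserves topology, sequences and tags
#' (read placements are not serialised).
#'
#' @param path path to a GFA1 file.
#' @return a `string_graph`.
#' @export
import_gfa <- function(path) {
  lines <- readLines(path)
  nodes <- list(); edges <- list()
  for (ln in lines) {
    if (ln == "" || startsWith(ln, "H")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (f[1] == "S") {
      if (length(f) < 3) stop("malformed GFA S line: ", ln)
      tags <- f[-(1:3)]
      getv <- function(p, cast, def) {
        hit <- tags[startsWith(tags, p)]
        if (length(hit) == 0) def else cast(sub(p, "", hit[1]))
      }
      nodes[[length(nodes) + 1L]] <- data.frame(
        id = f[2], bases = f[3], len = nchar(f[3]),
        support = getv("rd:i:", as.integer, 1L),
        depth = getv("dp:f:", as.numeric, 0),
        multiplicity = getv("ml:i:", as.integer, NA_integer_),
        stringsAsFactors = FALSE)
    } else if (f[1] == "L") {
      if (length(f) < 6) stop("malformed GFA L line: ", ln)
      edges[[length(edges) + 1L]] <- data.frame(
        from = f[2], from_orient = f[3], to = f[4], to_orient = f[5],
        len = as.integer(sub("M$", "", f[6])), stringsAsFactors = FALSE)
    }
  }
  nodes <- do.call(rbind, nodes) %||%
    data.frame(id = character(0), bases = character(0), len = integer(0),
               support = integer(0), depth = numeric(0),
               multiplicity = integer(0))
  edges <- do.call(rbind, edges) %||%
    data.frame(from = character(0), from_orient = character(0),
               to = character(0), to_orient = character(0), len = integer(0))
  structure(list(nodes = nodes, edges = edges,
                 placements = data.frame(node = character(0),
                                         read_id = character(0),
                                         offset = integer(0),
                                         orient = character(0),
                                         read_len = integer(0))),
            class = "string_graph")
}

#' @export
print.string_graph <- function(x, ...) {
  cat(sprintf("string graph: %d nodes, %d edges, %d placed reads\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$placements)))
  invisible(x)
}
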