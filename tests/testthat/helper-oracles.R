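# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately re-derive results from first principles,
# not by calling the implementation under test.

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# exhaustive microsatellite scan: for every period and start position,
# extend the maximal perfect tandem tract and apply the thresholds
oracle_microsats <- function(s, max_unit = 6L, min_length = 10L,
                             min_copies = 3L) {
  n <- nchar(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  tracts <- NULL
  for (p in seq_len(min(max_unit, n - 1L))) {
    st <- 1L
    while (st <= n - p) {
      if (ch[st] == ch[st + p]) {
        en <- st
        while (en <= n - p && ch[en] == ch[en + p]) en <- en + 1L
        tract_len <- (en - st) + p
        if (tract_len >= min_length && tract_len / p >= min_copies) {
          tracts <- rbind(tracts, data.frame(start = st - 1L,
                                             end = st - 1L + tract_len))
        }
        st <- en + 1L
      } else {
        st <- st + 1L
      }
    }
  }
  if (is.null(tracts)) return(data.frame(start = integer(0), end = integer(0)))
  # merge overlaps
  tracts <- tracts[order(tracts$start, tracts$end), , drop = FALSE]
  out <- tracts[1, ]
  for (i in seq_len(nrow(tracts))[-1]) {
    if (tracts$start[i] <= out$end[nrow(out)]) {
      out$end[nrow(out)] <- max(out$end[nrow(out)], tracts$end[i])
    } else {
      out <- rbind(out, tracts[i, ])
    }
  }
  rownames(out) <- NULL
  out
}

# NG50 by direct definition: the largest contig length L such that contigs
# of length >= L sum to at least half the genome size
oracle_ng50 <- function(lens, genome_size) {
  best <- NA_integer_
  for (L in sort(unique(lens))) {
    if (sum(lens[lens >= L]) >= genome_size / 2) best <- L
  }
  best
}

# all maximal exact suffix-prefix overlaps >= min_overlap between
# compressed reads (no masks), both orientations, by direct string search
oracle_overlaps <- function(bases, min_overlap) {
  n <- length(bases)
  rc <- graphasm::revcomp(bases)
  out <- NULL
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      for (a_or in c("+", "-")) {            # all four end-pairings
        a <- if (a_or == "+") bases[i] else rc[i]
        for (orient in c("+", "-")) {
          b <- if (orient == "+") bases[j] else rc[j]
          la <- nchar(a); lb <- nchar(b)
          if (min(la, lb) < min_overlap) next
          for (L in seq(min(la, lb), min_overlap)) {
            if (substr(a, la - L + 1L, la) == substr(b, 1L, L)) {
              if (L == min(la, lb)) next # containment-shaped; keep looking
              out <- rbind(out, data.frame(from = i, to = j, orient = orient,
                                           len = L))
              break # maximal proper dovetail
            }
          }
        }
      }
    }
  }
  out
}

# independent Eulerian-style enumeration of candidate walk sets over a
# multiplicity-annotated oriented graph; nodes indexed 1..n, edges as a
# data.frame(u, w) of oriented-vertex pairs (2i-1 = "+", 2i = "-",
# complements included). Walks start at in-degree-zero vertices and extend
# while possible; candidates are deduplicated up to walk orientation/order.
oracle_candidates <- function(n, vedges, mult) {
  flip <- function(v) ifelse(v %% 2L == 1L, v + 1L, v - 1L)
  node_of <- function(v) (v + 1L) %/% 2L
  out_of <- function(v) vedges$w[vedges$u == v]
  indeg0 <- vapply(seq_len(2L * n), function(v) !any(vedges$w == v), logical(1))
  sig_walk <- function(vs) {
    fwd <- paste(vs, collapse = " ")
    rev <- paste(rev(flip(vs)), collapse = " ")
    min(fwd, rev)
  }
  found <- new.env(parent = emptyenv())
  found$keys <- character(0)
  rec <- function(counts, walks, cur) {
    if (is.null(cur)) {
      if (all(counts == 0L)) {
        key <- paste(sort(vapply(walks, sig_walk, character(1))),
                     collapse = " | ")
        if (!(key %in% found$keys)) found$keys <- c(found$keys, key)
        return()
      }
      starts <- which(indeg0 & counts[node_of(seq_len(2L * n))] > 0L)
      if (length(starts) == 0L)
        starts <- min(which(counts[node_of(seq_len(2L * n))] > 0L))
      for (s in starts) {
        c2 <- counts; c2[node_of(s)] <- c2[node_of(s)] - 1L
        rec(c2, walks, s)
      }
    } else {
      v <- cur[length(cur)]
      nb <- out_of(v)
      nb <- nb[counts[node_of(nb)] > 0L]
      if (length(nb) == 0L) {
        rec(counts, c(walks, list(cur)), NULL)
      } else {
        for (w in unique(nb)) {
          c2 <- counts; c2[node_of(w)] <- c2[node_of(w)] - 1L
          rec(c2, walks, c(cur, w))
        }
      }
    }
  }
  rec(mult, list(), NULL)
  keys <- found$keys
  if (length(keys) > 1) {
    # parsimony: keep candidates with the fewest walks (see
    # enumerate_candidates)
    nw <- lengths(regmatches(keys, gregexpr(" \\| ", keys))) + 1L
    keys <- keys[nw == min(nw)]
  }
  sort(keys)
}

# build a minimal string_graph object for graph-algorithm tests
make_graph <- function(ids, lens, edges, depth = NULL, mult = NULL,
                       bases = NULL) {
  if (is.null(bases)) {
    bases <- vapply(lens, random_dna_str, character(1))
  }
  nodes <- data.frame(id = ids, bases = bases, len = nchar(bases),
                      support = rep(1L, length(ids)),
                      depth = depth %||% rep(30, length(ids)),
                      multiplicity = mult %||% rep(NA_integer_, length(ids)),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 placements = data.frame(node = character(0),
                                         read_id = character(0),
                                         offset = integer(0),
                                         orient = character(0),
                                         read_len = integer(0))),
            class = "string_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical signature of a candidate (list of walks) from the package's
# enumerate_candidates output, for comparison with oracle_candidates
cand_signature <- function(cand, ids) {
  flip <- function(v) ifelse(v %% 2L == 1L, v + 1L, v - 1L)
  vid_of <- function(steps) {
    i <- match(steps$node, ids)
    ifelse(steps$orient == "+", 2L * i - 1L, 2L * i)
  }
  sig_walk <- function(steps) {
    vs <- vid_of(steps)
    fwd <- paste(vs, collapse = " ")
    rev <- paste(rev(flip(vs)), collapse = " ")
    min(fwd, rev)
  }
  paste(sort(vapply(cand, function(w) sig_walk(w$steps), character(1))),
        collapse = " | ")
}
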