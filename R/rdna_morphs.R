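# Assembly of rDNA-like tandem arrays, which defeat the string graph due to
# their copy number: sparse de Bruijn graph over the array reads, noisy-read
# walk extraction (denoising), segmentation of walks into repeat units
# against a reference unit, single-linkage clustering of units into
# "morphs", read-support copy-number estimation, and a morph adjacency
# graph from which the array layout is derived (or, when reads cannot
# order the morphs, a block "model" layout flagged as such).

decode_kmer <- function(code, k) {
  ch <- character(k)
  for (i in k:1) {
    ch[i] <- c("A", "C", "G", "T")[code %% 4 + 1]
    code <- code %/% 4
  }
  paste(ch, collapse = "")
}

#' Build a sparse de Bruijn graph from reads
#'
#' Nodes are sampled k-mers (canonical k-mers whose hash is 0 mod
#' `sample_stride`, so all reads sample the same genome k-mers regardless
#' of their start or strand). A first pass counts the sampled k-mers; a
#' second pass records edges between consecutive *solid* k-mers (seen by
#' at least `min_count` reads) within each read, together with the
#' intervening sequence and a read count — so that noisy reads, which only
#' observe a subset of the solid k-mers cleanly, can still be threaded
#' through the graph. Both orientations of every edge are stored.
#'
#' @param reads data.frame with `id`, `bases`, or a character vector.
#' @param k k-mer size (>= 15 recommended; default 15).
#' @param sample_stride expected spacing between sampled k-mers (default
#'   20).
#' @param min_count solidity threshold for nodes (default 3).
#' @return object of class `sparse_dbg`: list with `k`, `stride`,
#'   `min_count`, `nodes` (data.table `code`, `count`) and `edges`
#'   (data.table `from`, `to` (oriented keys "code+"/"code-"), `step`
#'   (sequence appended by traversing the edge), `n`).
#' @export
build_sparse_dbg <- function(reads, k = 15L, sample_stride = 20L,
                             min_count = 3L) {
  if (is.character(reads)) reads <- data.frame(id = paste0("r", seq_along(reads)),
                                               bases = reads,
                                               stringsAsFactors = FALSE)
  n_skipped <- 0L
  scans <- vector("list", nrow(reads))
  node_counts <- list()
  for (r in seq_len(nrow(reads))) {
    bases <- reads$bases[r]
    if (nchar(bases) < k) {
      warning("read ", reads$id[r], " shorter than k; skipped")
      n_skipped <- n_skipped + 1L
      next
    }
    sc <- cpp_kmer_scan(bases, as.integer(k), as.integer(sample_stride))
    scans[[r]] <- sc
    if (nrow(sc) > 0)
      node_counts[[length(node_counts) + 1L]] <-
        data.table::data.table(code = unique(sc$code))
  }
  nodes <- if (length(node_counts))
    data.table::rbindlist(node_counts)[, list(count = .N), by = "code"]
  else data.table::data.table(code = numeric(0), count = integer(0))
  solid <- nodes$code[nodes$count >= min_count]
  edge_rows <- list()
  for (r in seq_len(nrow(reads))) {
    sc <- scans[[r]]
    if (is.null(sc) || nrow(sc) == 0) next
    sc <- sc[sc$code %in% solid, , drop = FALSE]
    m <- nrow(sc)
    if (m < 2) next
    bases <- reads$bases[r]
    key <- paste0(sc$code, ifelse(sc$fwd, "+", "-"))
    flipkey <- paste0(sc$code, ifelse(sc$fwd, "-", "+"))
    p <- sc$pos
    fwd_step <- substring(bases, p[-m] + k + 1L, p[-1] + k)
    rev_step <- revcomp(substring(bases, p[-m] + 1L, p[-1]))
    edge_rows[[length(edge_rows) + 1L]] <- data.table::data.table(
      from = c(key[-m], flipkey[-1]),
      to = c(key[-1], flipkey[-m]),
      step = c(fwd_step, rev_step))
  }
  edges <- if (length(edge_rows))
    data.table::rbindlist(edge_rows)[, list(n = .N), by = c("from", "to", "step")]
  else data.table::data.table(from = character(0), to = character(0),
                              step = character(0), n = integer(0))
  structure(list(k = as.integer(k), stride = as.integer(sample_stride),
                 min_count = as.integer(min_count), nodes = nodes,
                 edges = edges, n_skipped = n_skipped),
            class = "sparse_dbg")
}

#' Extract denoised walks for reads through a sparse de Bruijn graph
#'
#' Each read is threaded through the graph via the solid k-mers it
#' observes cleanly; between consecutive anchors the best-supported graph
#' path (widest path by edge read-count, length-consistent with the read)
#' is rendered from the modal edge sequences, replacing the read's own
#' sequence and thereby correcting most read errors. Stretches with no
#' supported path fall back to the read's own sequence. Reads with fewer
#' than `min_anchors` anchors are omitted (counted in attribute
#' `n_omitted`).
#'
#' @param ont_reads data.frame `id`, `bases`.
#' @param dbg a `sparse_dbg` built from a compatible read set.
#' @param min_anchors minimum solid anchors per read (default 2).
#' @param max_hops path search hop limit between anchors (default 12).
#' @return data.frame with `id`, `bases` (walk sequence); attribute
#'   `n_omitted`.
#' @export
extract_walks <- function(ont_reads, dbg, min_anchors = 2L, max_hops = 12L) {
  solid <- dbg$nodes$code[dbg$nodes$count >= dbg$min_count]
  e <- dbg$edges
  # The same oriented k-mer pair can recur at different separations in a
  # tandem array, so step variants are kept per edge and selected by
  # length at lookup time (best-supported variant of about the right
  # length; ties toward the smaller string).
  data.table::setorder(e, from, to, -n, step)
  e$steplen <- nchar(e$step)
  evar <- new.env(parent = emptyenv())
  ekeys <- paste(e$from, e$to)
  for (grp in split(seq_len(nrow(e)), ekeys)) {
    evar[[ekeys[grp[1]]]] <- list(step = e$step[grp], n = e$n[grp],
                                  len = e$steplen[grp])
  }
  lookup_step <- function(from, to, gap, min_n = 1L) {
    v <- evar[[paste(from, to)]]
    if (is.null(v)) return(list(step = NA_character_, n = 0L))
    ok <- abs(v$len - gap) <= pmax(4, 0.3 * gap) & v$n >= min_n
    if (!any(ok)) return(list(step = NA_character_, n = 0L))
    i <- which(ok)[1] # rows sorted by -n, step
    list(step = v$step[i], n = v$n[i])
  }
  # per source vertex, the best-supported short out-edge (greedy chain);
  # vertices whose second-best edge carries a substantial fraction of the
  # support are genuine branches (e.g. morph-distinguishing variants) and
  # must not be imputed from the graph majority — the read's own sequence
  # is used there instead
  eshort <- e[e$steplen <= 3L * dbg$stride, ]
  if (nrow(eshort) > 0) {
    tot <- eshort[, list(ntot = sum(n)), by = c("from", "to", "steplen")]
    data.table::setorder(tot, from, -ntot, to)
    eb <- tot[!duplicated(tot$from), ]
    second <- tot[duplicated(tot$from), ]
    second <- second[!duplicated(second$from), ]
    sec_n <- setNames(second$ntot, second$from)
    eb$step <- vapply(seq_len(nrow(eb)), function(i)
      lookup_step(eb$from[i], eb$to[i], eb$steplen[i])$step, character(1))
    ambiguous <- eb$from[!is.na(sec_n[eb$from]) &
                           sec_n[eb$from] >= 0.25 * eb$ntot]
    best_to <- setNames(eb$to, eb$from)
    best_step <- setNames(eb$step, eb$from)
  } else {
    best_to <- character(0)
    best_step <- character(0)
    ambiguous <- character(0)
  }
  # follow best-supported short edges from -> to within a length budget
  find_path <- function(from, to, max_len) {
    cur <- from
    acc <- character(0)
    len <- 0L
    for (hop in seq_len(max_hops)) {
      if (cur %in% ambiguous) return(NA_character_)
      nxt <- best_to[cur]
      if (is.na(nxt) || is.null(nxt)) return(NA_character_)
      st <- best_step[cur]
      if (is.na(st)) return(NA_character_)
      len <- len + nchar(st)
      if (len > max_len) return(NA_character_)
      acc <- c(acc, st)
      if (nxt == to) return(paste(acc, collapse = ""))
      cur <- nxt
    }
    NA_character_
  }
  out <- list(); omitted <- 0L
  for (r in seq_len(nrow(ont_reads))) {
    bases <- ont_reads$bases[r]
    if (nchar(bases) < dbg$k) { omitted <- omitted + 1L; next }
    sc <- cpp_kmer_scan(bases, dbg$k, dbg$stride)
    sc <- sc[sc$code %in% solid, , drop = FALSE]
    if (nrow(sc) < min_anchors) { omitted <- omitted + 1L; next }
    key <- paste0(sc$code, ifelse(sc$fwd, "+", "-"))
    first <- decode_kmer(sc$code[1], dbg$k)
    if (!sc$fwd[1]) first <- revcomp(first)
    parts <- character(nrow(sc))
    parts[1] <- first
    for (j in seq_len(nrow(sc) - 1L)) {
      gap <- sc$pos[j + 1L] - sc$pos[j]
      # thread along the best-supported short edges; the read's own
      # anchors pin the route at morph-distinguishing positions
      step <- find_path(key[j], key[j + 1L], max_len = gap + 0.3 * gap + 20)
      if (!is.na(step) && abs(nchar(step) - gap) > 0.3 * gap + 20)
        step <- NA_character_
      if (is.na(step)) {
        # fall back to the read's own sequence for this stretch
        step <- substr(bases, sc$pos[j] + dbg$k + 1L, sc$pos[j + 1L] + dbg$k)
      }
      parts[j + 1L] <- step
    }
    out[[length(out) + 1L]] <- data.frame(
      id = ont_reads$id[r], bases = paste(parts, collapse = ""),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out) %||% data.frame(id = character(0),
                                             bases = character(0))
  attr(res, "n_omitted") <- omitted
  res
}

#' Segment an array sequence into repeat units
#'
#' Locates approximate occurrences of the reference unit origin (its
#' leading bases) along the sequence; units run origin-to-origin, so the
#' unit phase is defined by position 0 of the reference. Complete units
#' must be within 10% of the reference length and align to the reference
#' at `min_identity` or better; flanking partial units are marked
#' `complete = FALSE`.
#'
#' @param bases array or walk sequence (single string).
#' @param unit_reference the reference unit sequence.
#' @param min_identity minimum percent identity/100 for a complete unit
#'   (default 0.9).
#' @param source id recorded on the returned units.
#' @return data.frame with `source`, `ordinal`, `start`, `end`, `bases`,
#'   `complete`.
#' @export
segment_units <- function(bases, unit_reference, min_identity = 0.9,
                          source = "seq") {
  ulen <- nchar(unit_reference)
  seed_len <- min(32L, max(12L, ulen %/% 4L))
  seed <- substr(unit_reference, 1, seed_len)
  mm <- max(1L, ceiling(seed_len * (1 - min_identity)))
  hits <- Biostrings::matchPattern(seed, Biostrings::DNAString(bases),
                                   max.mismatch = mm, with.indels = TRUE)
  starts <- sort(Biostrings::start(hits)) - 1L # 0-based
  # dedupe clustered hits
  if (length(starts) > 1) {
    keep <- c(TRUE, diff(starts) > ulen / 2)
    starts <- starts[keep]
  }
  empty <- data.frame(source = character(0), ordinal = integer(0),
                      start = integer(0), end = integer(0),
                      bases = character(0), complete = logical(0),
                      stringsAsFactors = FALSE)
  if (length(starts) == 0) return(empty)
  bounds <- c(starts, nchar(bases))
  rows <- list()
  ordinal <- 0L
  if (starts[1] > 0L) {
    ordinal <- ordinal + 1L
    rows[[1]] <- data.frame(source = source, ordinal = ordinal, start = 0L,
                            end = starts[1],
                            bases = substr(bases, 1, starts[1]),
                            complete = FALSE, stringsAsFactors = FALSE)
  }
  for (i in seq_along(starts)) {
    s <- bounds[i]; e <- bounds[i + 1L]
    if (i == length(starts) && (e - s) > 1.1 * ulen) {
      # trailing flank glued to the last unit: split the unit off
      e <- min(e, s + ulen)
    }
    u <- substr(bases, s + 1L, e)
    ordinal <- ordinal + 1L
    complete <- abs((e - s) - ulen) <= 0.1 * ulen &&
      seq_identity(u, unit_reference, band = max(50L, ceiling(0.2 * ulen))) >=
        100 * min_identity
    rows[[length(rows) + 1L]] <- data.frame(
      source = source, ordinal = ordinal, start = s, end = e, bases = u,
      complete = complete, stringsAsFactors = FALSE)
    if (i == length(starts) && e < bounds[i + 1L]) {
      ordinal <- ordinal + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        source = source, ordinal = ordinal, start = e, end = bounds[i + 1L],
        bases = substr(bases, e + 1L, bounds[i + 1L]), complete = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Polish repeat units in reference coordinates
#'
#' Each complete unit is aligned (affine-gap, global) to the reference
#' unit and projected onto its columns (insertions relative to the
#' reference are dropped); every column is then corrected to the majority
#' symbol across units, except *polymorphic* columns — where the majority
#' does not dominate the rest of the column by `min_support_ratio` — which
#' are never corrected, for anyone: that is where morph-level variation
#' lives. A second phase repairs haplotype-inconsistent units: a unit
#' whose genotype over the polymorphic columns lies within one-third
#' Hamming distance of exactly one well-supported pattern carries a
#' sequencing error at a protected column and is repaired to that
#' pattern. Sequencing noise is thus removed while morph variants
#' (present in a substantial minority of units) are preserved.
#' Working in reference coordinates collapses length variation between
#' units; morphs distinguished only by insertions relative to the
#' reference are not separable after this polish.
#'
#' @param units data.frame from [segment_units()].
#' @param unit_reference the reference unit sequence.
#' @param min_depth minimum majority support for a correction (default 4).
#' @param min_support_ratio majority versus rest-of-column dominance ratio
#'   (default 4).
#' @return `units` with polished `bases` for complete units.
#' @export
polish_units <- function(units, unit_reference, min_depth = 4L,
                         min_support_ratio = 4) {
  comp <- which(units$complete)
  if (length(comp) < 2) return(units)
  seqs <- units$bases[comp]
  ulen <- nchar(unit_reference)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(seqs), Biostrings::DNAString(unit_reference),
    type = "global")
  apat <- as.character(Biostrings::alignedPattern(pa))
  asub <- as.character(Biostrings::alignedSubject(pa))
  mat <- matrix("-", length(seqs), ulen)
  for (i in seq_along(seqs)) {
    pc <- strsplit(apat[i], "", fixed = TRUE)[[1]]
    sc <- strsplit(asub[i], "", fixed = TRUE)[[1]]
    mat[i, ] <- pc[sc != "-"]
  }
  syms <- c("A", "C", "G", "T", "-")
  cnt <- vapply(syms, function(s) colSums(mat == s), numeric(ulen))
  if (ulen == 1) cnt <- matrix(cnt, nrow = 1, dimnames = list(NULL, syms))
  maj_i <- max.col(cnt, ties.method = "first")
  maj_n <- cnt[cbind(seq_len(ulen), maj_i)]
  tie <- rowSums(cnt == maj_n) > 1L
  total <- rowSums(cnt)
  correctable <- !tie & maj_n >= min_depth &
    maj_n >= min_support_ratio * pmax(1, total - maj_n)
  for (i in seq_along(seqs)) {
    own <- mat[i, ]
    repl <- correctable & syms[maj_i] != own
    mat[i, repl] <- syms[maj_i][repl]
  }
  # haplotype-consistency repair at the polymorphic columns: alleles of a
  # morph co-occur, so a unit whose genotype is one step away from a
  # well-supported pattern (and far from every other) carries a sequencing
  # error at that column — the one error class per-column majorities can
  # never fix, because the columns are protected
  poly <- which(!tie & (total - maj_n) >= pmax(min_depth, 0.15 * total))
  if (length(poly) >= 2 && length(seqs) >= 10) {
    geno <- apply(mat[, poly, drop = FALSE], 1, paste, collapse = "")
    tab <- table(geno)
    major <- names(tab)[tab >= max(3, 0.08 * length(seqs))]
    if (length(major) >= 1) {
      major_m <- do.call(rbind, strsplit(major, "", fixed = TRUE))
      tol <- max(1, floor(length(poly) / 3))
      for (i in seq_along(seqs)) {
        if (geno[i] %in% major) next
        dists <- rowSums(major_m != matrix(mat[i, poly], nrow(major_m),
                                           length(poly), byrow = TRUE))
        ok <- which(dists <= tol)
        if (length(ok) == 1) mat[i, poly] <- major_m[ok, ]
      }
    }
  }
  out <- units
  for (i in seq_along(seqs)) {
    res <- mat[i, ]
    out$bases[comp[i]] <- paste(res[res != "-"], collapse = "")
  }
  out
}

# majority consensus of a cluster of near-identical unit sequences:
# the medoid is corrected by simple majority over the member alignments
cluster_consensus <- function(seqs) {
  n <- length(seqs)
  if (n == 1) return(seqs)
  ids <- vapply(seqs, function(a) sum(vapply(seqs, function(b)
    seq_identity(a, b, band = 64L), numeric(1))), numeric(1))
  medoid <- which.max(ids)
  queries <- seqs[-medoid]
  res <- cpp_correct_read(seqs[medoid], queries, rep(0L, length(queries)),
                          64L, rep(FALSE, nchar(seqs[medoid])),
                          as.integer(max(2L, floor(n / 2) + 1L)), 1.0)
  res$bases
}

#' Cluster repeat units into morphs
#'
#' Single-linkage clustering of complete units at the given pairwise
#' identity threshold; each cluster's consensus is the majority vote over
#' its members. Optionally polished with accurate reads via the same
#' majority rule. Clustering is invariant to input order.
#'
#' @param units data.frame from [segment_units()] (rows with
#'   `complete == FALSE` are ignored).
#' @param identity_threshold minimum within-morph pairwise identity as a
#'   fraction (default 0.995).
#' @param hifi_reads optional data.frame of accurate reads for a polishing
#'   pass.
#' @return list with `morphs` (data.frame `id`, `bases`, `n_units`,
#'   `supporting_reads`) and `assignment` (morph id per row of `units`,
#'   NA for incomplete units).
#' @export
cluster_morphs <- function(units, identity_threshold = 0.995,
                           hifi_reads = NULL) {
  comp <- which(units$complete)
  if (length(comp) == 0) stop("no complete units to cluster")
  seqs <- units$bases[comp]
  n <- length(seqs)
  cl <- if (n == 1) 1L else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- 100 - seq_identity(seqs[i], seqs[j], band = 64L)
      }
    }
    hc <- stats::hclust(stats::as.dist(d), method = "single")
    stats::cutree(hc, h = 100 * (1 - identity_threshold))
  }
  # stable morph ids: by decreasing cluster size, ties by first occurrence
  sizes <- table(cl)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  cl <- relabel[as.character(cl)]
  morphs <- lapply(sort(unique(cl)), function(m) {
    member <- comp[cl == m]
    cons <- cluster_consensus(units$bases[member])
    data.frame(id = sprintf("morph%d", m), bases = cons,
               n_units = length(member),
               supporting_reads = paste(sort(unique(units$source[member])),
                                        collapse = ","),
               stringsAsFactors = FALSE)
  })
  morphs <- do.call(rbind, morphs)
  if (!is.null(hifi_reads) && nrow(hifi_reads) > 0) {
    morphs$bases <- vapply(morphs$bases, polish_with_reads,
                           character(1), reads = hifi_reads)
  }
  assignment <- rep(NA_character_, nrow(units))
  assignment[comp] <- sprintf("morph%d", cl)
  list(morphs = morphs, assignment = assignment)
}

# polish a consensus with matching segments of accurate reads (majority
# rule, as in cluster_consensus)
polish_with_reads <- function(consensus, reads, k = 21L, w = 5L) {
  cs <- cpp_kmer_scan(consensus, as.integer(k), as.integer(w))
  if (nrow(cs) == 0) return(consensus)
  cdt <- data.table::data.table(code = cs$code, cpos = cs$pos, cfwd = cs$fwd)
  segs <- character(0); diags <- integer(0)
  for (r in seq_len(nrow(reads))) {
    rs <- cpp_kmer_scan(reads$bases[r], as.integer(k), as.integer(w))
    if (nrow(rs) == 0) next
    m <- merge(data.table::data.table(code = rs$code, rpos = rs$pos,
                                      rfwd = rs$fwd), cdt, by = "code")
    if (nrow(m) < 3) next
    ori <- ifelse(m$rfwd == m$cfwd, "+", "-")
    main <- names(sort(table(ori), decreasing = TRUE))[1]
    m <- m[ori == main, ]
    rp <- if (main == "+") m$rpos else nchar(reads$bases[r]) - k - m$rpos
    dg <- m$cpos - rp
    d <- as.integer(median(dg))
    segs <- c(segs, if (main == "+") reads$bases[r] else revcomp(reads$bases[r]))
    diags <- c(diags, d)
  }
  if (length(segs) < 4) return(consensus)
  res <- cpp_correct_read(consensus, segs, diags, 48L,
                          rep(FALSE, nchar(consensus)),
                          as.integer(max(2L, floor(length(segs) / 2) + 1L)), 1.0)
  res$bases
}

#' Identify walks spanning the whole array
#'
#' A walk spans the array iff both of its terminal (incomplete) segments
#' are flanking sequence rather than mid-unit fragments: a terminal piece
#' is flank-like when it aligns poorly to the corresponding end of the
#' reference unit.
#'
#' @param units data.frame from [segment_units()] over per-walk segments.
#' @param unit_reference the reference unit sequence.
#' @param min_piece minimum terminal piece length considered informative.
#' @param max_unit_like identity (%) above which a terminal piece counts
#'   as a unit fragment (default 75).
#' @return character vector of spanning source ids.
#' @export
spanning_walks <- function(units, unit_reference, min_piece = 30L,
                           max_unit_like = 75) {
  ulen <- nchar(unit_reference)
  flank_like <- function(piece, side) {
    n <- nchar(piece)
    if (n < min_piece) return(FALSE) # too short to judge
    n <- min(n, ulen)
    ref_part <- if (side == "first") {
      substr(unit_reference, ulen - n + 1L, ulen) # piece precedes an origin
    } else {
      substr(unit_reference, 1L, n)
    }
    piece_part <- if (side == "first") substr(piece, nchar(piece) - n + 1L, nchar(piece))
                  else substr(piece, 1L, n)
    seq_identity(piece_part, ref_part, band = max(32L, ceiling(0.3 * n))) <
      max_unit_like
  }
  ok <- vapply(split(seq_len(nrow(units)), units$source), function(ii) {
    d <- units[ii[order(units$ordinal[ii])], , drop = FALSE]
    nrow(d) >= 3 && !d$complete[1] && !d$complete[nrow(d)] &&
      flank_like(d$bases[1], "first") &&
      flank_like(d$bases[nrow(d)], "last")
  }, logical(1))
  names(ok)[ok]
}

# round to nearest, ties away from zero (ties up for positives)
round_half_up <- function(x) floor(x + 0.5)

#' Estimate morph copy numbers from read support
#'
#' copy_number = units assigned to the morph across reads, divided by the
#' mean read depth over units, rounded to the nearest integer (ties up)
#' with a minimum of 1 for any observed morph.
#'
#' @param morphs morph table from [cluster_morphs()] (`$morphs`).
#' @param unit_depth mean sequencing depth over the array units (e.g. the
#'   ONT depth used to generate the walks).
#' @return the morph table with a `copy_number` column.
#' @export
estimate_copy_number <- function(morphs, unit_depth) {
  if (is.null(unit_depth) || unit_depth <= 0) stop("unit depth must be > 0")
  morphs$copy_number <- pmax(1L, round_half_up(morphs$n_units / unit_depth))
  morphs
}

#' Total array copies from short-read depth
#'
#' Depth ratio of the array to the genome-wide base depth, interpreted as
#' the total number of unit copies per assembled unit.
#'
#' @param array_depth mean short-read depth across the array.
#' @param base_depth genome-wide base depth.
#' @return the (possibly fractional) copy estimate.
#' @export
estimate_array_copies_by_depth <- function(array_depth, base_depth) {
  if (base_depth <= 0) stop("base_depth must be > 0")
  array_depth / base_depth
}

#' Build the morph adjacency graph
#'
#' Directed edges between morphs observed consecutively (by ordinal)
#' within the same read/walk, weighted by the number of observations.
#'
#' @param units data.frame from [segment_units()] over the per-read walks.
#' @param assignment morph assignment per unit row (from
#'   [cluster_morphs()]).
#' @return list with `nodes` (morph ids) and `edges` (data.frame `from`,
#'   `to`, `weight`), plus `paths`: the per-read morph sequences.
#' @export
build_morph_graph <- function(units, assignment) {
  u <- units
  u$morph <- assignment
  u <- u[!is.na(u$morph), , drop = FALSE]
  paths <- lapply(split(u[order(u$ordinal), ], u$source[order(u$ordinal)]),
                  function(d) d$morph[order(d$ordinal)])
  edges <- list()
  for (p in paths) {
    if (length(p) >= 2) {
      edges[[length(edges) + 1L]] <- data.frame(
        from = p[-length(p)], to = p[-1], stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) {
    e <- do.call(rbind, edges)
    agg <- as.data.frame(table(e$from, e$to), stringsAsFactors = FALSE)
    names(agg) <- c("from", "to", "weight")
    agg[agg$weight > 0, , drop = FALSE]
  } else data.frame(from = character(0), to = character(0),
                    weight = integer(0))
  rownames(edges) <- NULL
  list(nodes = sort(unique(u$morph)), edges = edges, paths = paths)
}

#' Lay out a tandem array from its morph graph
#'
#' Searches for unit orders consistent with the morph copy numbers, the
#' observed adjacencies, and every read's observed morph sequence (as a
#' contiguous subsequence). If exactly one order survives, it is emitted
#' with `model = FALSE`; otherwise the morphs are arranged in consecutive
#' blocks by descending copy number and the layout is flagged
#' `model = TRUE` (a model sequence whose unit order is not fully
#' read-supported).
#'
#' @param morph_graph output of [build_morph_graph()].
#' @param copy_numbers named integer vector (morph id -> copy number).
#' @param max_orders enumeration cap (default 5000).
#' @return list with `order` (character vector of morph ids) and `model`
#'   (logical).
#' @export
layout_array <- function(morph_graph, copy_numbers, max_orders = 5000L) {
  morphs <- names(copy_numbers)
  total <- sum(copy_numbers)
  blocks <- rep(names(sort(copy_numbers, decreasing = TRUE)),
                sort(copy_numbers, decreasing = TRUE))
  ek <- paste(morph_graph$edges$from, morph_graph$edges$to)
  if (nrow(morph_graph$edges) == 0) {
    if (total == 1L) return(list(order = blocks, model = FALSE))
    return(list(order = blocks, model = TRUE))
  }
  found <- list()
  n_found <- 0L
  steps <- 0L
  truncated <- FALSE
  rec <- function(seqv, counts) {
    if (truncated) return()
    steps <<- steps + 1L
    if (steps > 50L * max_orders || n_found > max_orders) {
      truncated <<- TRUE
      return()
    }
    if (length(seqv) == total) {
      n_found <<- n_found + 1L
      found[[n_found]] <<- seqv
      return()
    }
    for (m in morphs) {
      if (counts[m] == 0L) next
      if (length(seqv) > 0 &&
          !(paste(seqv[length(seqv)], m) %in% ek)) next
      c2 <- counts; c2[m] <- c2[m] - 1L
      rec(c(seqv, m), c2)
    }
  }
  rec(character(0), copy_numbers)
  multi <- Filter(function(p) length(p) >= 2, morph_graph$paths)
  if (length(multi) == 0) return(list(order = blocks, model = TRUE))
  # reads spanning the whole array observe the order directly; their paths
  # are candidate orders too (robust to an off-by-one copy-number total)
  plen <- vapply(multi, length, integer(1))
  full <- multi[plen >= max(max(plen), total - 1L)]
  found <- unique(c(found, full))
  if (truncated || length(found) == 0) return(list(order = blocks, model = TRUE))
  # score each order by the read paths it contains; a few paths may carry
  # unit-assignment errors, so the winner needs most (not all) of them
  score <- vapply(found, function(o) {
    hay <- paste0(" ", paste(o, collapse = " "), " ")
    sum(vapply(multi, function(p)
      grepl(paste0(" ", paste(p, collapse = " "), " "), hay, fixed = TRUE),
      logical(1)))
  }, integer(1))
  ord <- order(score, decreasing = TRUE)
  runner <- if (length(ord) > 1) score[ord[2]] else -1L
  if (score[ord[1]] >= 0.6 * length(multi) && score[ord[1]] > runner)
    return(list(order = found[[ord[1]]], model = FALSE))
  list(order = blocks, model = TRUE)
}

#' End-to-end morph analysis of an rDNA-like tandem array
#'
#' Segments each read into repeat units against the reference unit,
#' polishes the units in reference coordinates, clusters them into
#' morphs, estimates copy numbers from the array-spanning reads, and lays
#' out the array from the morph graph (flagged as a model sequence when
#' the reads cannot order the morphs).
#'
#' @param reads data.frame `id`, `bases` (ultra-long reads over the
#'   array, or denoised walks).
#' @param unit_reference the reference unit sequence.
#' @param identity_threshold morph clustering threshold (default 0.995).
#' @param copy_numbers optional externally estimated copy numbers (named
#'   by morph id); required when no read spans the whole array.
#' @param max_cluster_units single-linkage clustering runs on at most
#'   this many (evenly spaced) units; the rest are assigned to the
#'   nearest morph consensus. Single linkage over very many units becomes
#'   bridge-sensitive: every additional unit is another chance for a
#'   noisy intermediate to chain two morphs together.
#' @return list with `units`, `morphs` (with `copy_number`),
#'   `assignment`, `morph_graph`, `layout` (`order`, `model`) and
#'   `n_spanning`.
#' @export
analyze_rdna_array <- function(reads, unit_reference,
                               identity_threshold = 0.995,
                               copy_numbers = NULL,
                               max_cluster_units = 250L) {
  # units are segmented in the reference orientation only; reads from the
  # opposite strand contribute no units (the arrays carry no inversions,
  # so every unit that is found is head-to-tail by construction)
  units <- do.call(rbind, lapply(seq_len(nrow(reads)), function(i)
    segment_units(reads$bases[i], unit_reference, source = reads$id[i])))
  if (is.null(units) || sum(units$complete) == 0)
    stop("no complete units found")
  units <- polish_units(units, unit_reference)
  comp_idx <- which(units$complete)
  sub <- comp_idx
  if (length(sub) > max_cluster_units)
    sub <- sub[round(seq(1, length(sub), length.out = max_cluster_units))]
  # single linkage is bridge-sensitive: one chimeric unit (a residual
  # polishing artifact mixing morph alleles) chains two morphs together.
  # Real morph units have many near-identical twins; chimeras are rare
  # allele combinations and have none. Only twinned units enter the
  # clustering; everything is assigned to a morph consensus afterwards.
  twin_id <- 100 - 50 * (1 - identity_threshold) # halfway to 100%
  n <- length(sub)
  if (n > 2) {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- seq_identity(units$bases[sub[i]],
                                           units$bases[sub[j]], band = 64L)
      }
    }
    twins <- vapply(seq_len(n), function(i) sum(d[i, -i] >= twin_id),
                    integer(1))
    if (any(twins >= 2)) sub <- sub[twins >= 2]
  }
  cm_sub <- cluster_morphs(units[sub, , drop = FALSE], identity_threshold)
  assignment <- rep(NA_character_, nrow(units))
  for (i in comp_idx) {
    ids <- vapply(cm_sub$morphs$bases, seq_identity, numeric(1),
                  b = units$bases[i], band = 64L)
    assignment[i] <- cm_sub$morphs$id[which.max(ids)]
  }
  morph_tab <- cm_sub$morphs
  morph_tab$n_units <- vapply(morph_tab$id, function(x)
    sum(assignment == x, na.rm = TRUE), integer(1))
  cm <- list(morphs = morph_tab, assignment = assignment)
  span <- spanning_walks(units, unit_reference)
  morphs <- cm$morphs
  if (is.null(copy_numbers)) {
    if (length(span) == 0)
      stop("no array-spanning reads; supply copy_numbers explicitly")
    insp <- units$source %in% span
    morphs$n_units <- vapply(morphs$id, function(x)
      sum(cm$assignment == x & insp, na.rm = TRUE), integer(1))
    morphs <- morphs[morphs$n_units > 0, , drop = FALSE]
    morphs <- estimate_copy_number(morphs, length(span))
    copy_numbers <- setNames(morphs$copy_number, morphs$id)
  } else {
    morphs <- morphs[morphs$id %in% names(copy_numbers), , drop = FALSE]
    morphs$copy_number <- as.integer(copy_numbers[morphs$id])
  }
  mg <- build_morph_graph(units, cm$assignment)
  lay <- layout_array(mg, copy_numbers)
  list(units = units, morphs = morphs, assignment = cm$assignment,
       morph_graph = mg, layout = lay, n_spanning = length(span))
}

#' Write morph consensus sequences as FASTA with header tags
#'
#' @param morphs morph table with `copy_number` (see
#'   [estimate_copy_number()]).
#' @param path output path.
#' @param model model-array flag recorded in every header.
#' @export
write_morphs <- function(morphs, path, model = FALSE) {
  ids <- sprintf("%s cn=%d model=%s", morphs$id, morphs$copy_number,
                 ifelse(model, "true", "false"))
  write_fasta(data.frame(id = ids, bases = morphs$bases), path)
}
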