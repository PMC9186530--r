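# All-vs-all alignment of homopolymer-compressed reads, majority-vote error
# correction with simple-sequence-repeat masking, and exact suffix-prefix
# overlap detection. Everything here operates in compressed space.

#' Compress a read table into an hpc_set
#'
#' @param reads data.frame with `id`, `bases` (and optional metadata, kept).
#' @return object of class `hpc_set`: list with `id`, `bases` (compressed),
#'   `runs` (list of integer run-length vectors) and `meta` (the input table
#'   minus bases).
#' @export
hpc_compress_set <- function(reads) {
  hs <- lapply(seq_len(nrow(reads)), function(i)
    hpc_compress(reads$bases[i], reads$id[i]))
  structure(list(id = reads$id,
                 bases = vapply(hs, `[[`, character(1), "bases"),
                 runs = lapply(hs, `[[`, "run_lengths"),
                 meta = reads[, setdiff(names(reads), "bases"), drop = FALSE]),
            class = "hpc_set")
}

#' Subset an hpc_set by read index
#'
#' @param hpc an `hpc_set`.
#' @param keep integer or logical index of reads to keep.
#' @return the subset `hpc_set`.
#' @export
hpc_subset <- function(hpc, keep) {
  structure(list(id = hpc$id[keep], bases = hpc$bases[keep],
                 runs = hpc$runs[keep],
                 meta = hpc$meta[keep, , drop = FALSE]),
            class = "hpc_set")
}

#' Detect simple-sequence-repeat masks on a compressed read set
#'
#' Runs [find_microsatellites()] on each compressed read. Masking lives in
#' compressed space because correction and overlapping operate there.
#'
#' @param hpc an `hpc_set`.
#' @param ... passed to [find_microsatellites()].
#' @return data.frame of mask intervals (`seq_id`, `start`, `end`, `unit`).
#' @export
mask_reads <- function(hpc, ...) {
  out <- lapply(seq_along(hpc$id), function(i)
    find_microsatellites(hpc$bases[i], seq_id = hpc$id[i], ...))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# data.table of sampled k-mers over a set of strings
read_seeds <- function(bases, k, w) {
  dts <- lapply(seq_along(bases), function(i) {
    df <- cpp_kmer_scan(bases[i], as.integer(k), as.integer(w))
    if (nrow(df) == 0) return(NULL)
    data.table::data.table(read = i, pos = df$pos, code = df$code, fwd = df$fwd)
  })
  data.table::rbindlist(dts)
}

# candidate read pairs from shared seeds: returns data.table
# (a, b, strand, diag, n_seeds) with a < b; diag places oriented-b onto a
# (a_pos = b_pos + diag; b coordinates in its oriented frame).
pair_candidates <- function(seeds, lens, k, max_occ = 200L, min_seeds = 2L,
                            diag_tol = 0L) {
  empty <- data.table::data.table(a = integer(0), b = integer(0),
                                  strand = character(0), diag = integer(0),
                                  n_seeds = integer(0))
  if (is.null(seeds) || nrow(seeds) == 0) return(empty)
  cnt <- seeds[, list(nocc = .N), by = "code"]
  seeds <- merge(seeds, cnt[cnt$nocc <= max_occ, "code"], by = "code")
  if (nrow(seeds) == 0) return(empty)
  m <- merge(seeds, seeds, by = "code", allow.cartesian = TRUE,
             suffixes = c(".a", ".b"))
  m <- m[m$read.a < m$read.b, ]
  if (nrow(m) == 0) return(empty)
  m$strand <- ifelse(m$fwd.a == m$fwd.b, "+", "-")
  posb <- ifelse(m$strand == "+", m$pos.b, lens[m$read.b] - k - m$pos.b)
  m$diag <- m$pos.a - posb
  grp <- m[, list(n_seeds = .N),
           by = c("read.a", "read.b", "strand", "diag")]
  data.table::setnames(grp, c("read.a", "read.b"), c("a", "b"))
  data.table::setorder(grp, a, b, strand, -n_seeds)
  if (diag_tol > 0L) {
    # greedy clustering of nearby diagonals, keeping the best-supported one
    grp <- grp[, {
      keep <- logical(.N)
      used <- rep(FALSE, .N)
      for (i in seq_len(.N)) {
        if (used[i]) next
        keep[i] <- TRUE
        near <- abs(diag - diag[i]) <= diag_tol
        n_seeds[i] <- sum(n_seeds[near & !used])
        used <- used | near
      }
      list(diag = diag[keep], n_seeds = n_seeds[keep])
    }, by = c("a", "b", "strand")]
  }
  grp[grp$n_seeds >= min_seeds, ]
}

# lazily computed reverse complements of an hpc_set's compressed bases
oriented_bases <- function(hpc, idx, strand) {
  if (strand == "+") hpc$bases[idx] else revcomp(hpc$bases[idx])
}

#' All-vs-all approximate alignment of compressed reads
#'
#' Seeded (shared sampled k-mers) candidate detection followed by banded
#' overlap alignment. Both orientations are considered. Returned alignments
#' are canonicalised with `a < b` (by read index); `diag` places the
#' oriented b read onto a (a_pos = b_pos + diag, b positions counted in its
#' aligned orientation).
#'
#' @param hpc an `hpc_set` of compressed reads.
#' @param min_overlap minimum overlap length in compressed bases (default
#'   500).
#' @param min_identity identity floor for reported alignments (default
#'   0.98, the accurate-read regime).
#' @param k seed k-mer size (compressed space, default 21).
#' @param w seed sampling rate: k-mers with hash %% w == 0 are used
#'   (default 50).
#' @param band alignment band half-width (default 12).
#' @param max_verify identity is verified on a leading slice of at most
#'   this many bases of the overlap (screening, not layout; default 4000).
#' @param max_occ,min_seeds repeat filter and minimum seed count per
#'   candidate.
#' @return data.frame with columns `a`, `b` (read ids), `a_idx`, `b_idx`,
#'   `strand`, `diag`, `len`, `dist`, `identity`.
#' @export
all_pairs_align <- function(hpc, min_overlap = 500L, min_identity = 0.98,
                            k = 21L, w = 50L, band = 12L, max_occ = 200L,
                            min_seeds = 2L, max_verify = 4000L) {
  stopifnot(min_overlap >= 1L)
  lens <- nchar(hpc$bases)
  seeds <- read_seeds(hpc$bases, k, w)
  cand <- pair_candidates(seeds, lens, k, max_occ, min_seeds,
                          diag_tol = band)
  if (nrow(cand) == 0) {
    return(data.frame(a = character(0), b = character(0), a_idx = integer(0),
                      b_idx = integer(0), strand = character(0),
                      diag = integer(0), len = integer(0), dist = integer(0),
                      identity = numeric(0)))
  }
  rc_cache <- new.env(parent = emptyenv())
  get_rc <- function(i) {
    key <- as.character(i)
    if (is.null(rc_cache[[key]])) rc_cache[[key]] <- revcomp(hpc$bases[i])
    rc_cache[[key]]
  }
  nc <- nrow(cand)
  len_v <- integer(nc); dist_v <- integer(nc); keep <- logical(nc)
  for (r in seq_len(nc)) {
    ai <- cand$a[r]; bi <- cand$b[r]
    bseq <- if (cand$strand[r] == "+") hpc$bases[bi] else get_rc(bi)
    la <- nchar(hpc$bases[ai]); lb <- nchar(bseq); d <- cand$diag[r]
    full_len <- min(la - max(0L, d), lb - max(0L, -d))
    if (full_len < min_overlap) next
    od <- cpp_overlap_dist(hpc$bases[ai], bseq, d, band, max_verify)
    if (is.na(od$dist)) next
    if (1 - od$dist / od$len < min_identity) next
    len_v[r] <- full_len; dist_v[r] <- od$dist; keep[r] <- TRUE
  }
  out <- data.frame(a = hpc$id[cand$a[keep]], b = hpc$id[cand$b[keep]],
                    a_idx = cand$a[keep], b_idx = cand$b[keep],
                    strand = cand$strand[keep], diag = cand$diag[keep],
                    len = len_v[keep], dist = dist_v[keep],
                    identity = 1 - dist_v[keep] / pmax(1L, pmin(len_v[keep], max_verify)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Majority-vote correction of compressed reads
#'
#' At each pileup column of a read (outside its masks), the read's symbol is
#' replaced by the strict-majority symbol among aligned partner reads iff the
#' majority has support of at least `min_depth` reads and at least
#' `min_support_ratio` times the read's own symbol count. Substitutions,
#' spurious bases (majority gap) and missing bases (majority insertion) are
#' all corrected. Masked (simple-sequence-repeat) columns are protected by
#' a much stricter super-majority (`mask_ratio`, default twice
#' `min_support_ratio`): genuine repeat polymorphism splits the pileup and
#' is preserved, while repeat-length sequencing errors are normalised
#' toward the consensus tract — a prerequisite for position-wise exact
#' overlapping. A single pass over the original (uncorrected) read set is
#' performed, so correction is order-independent and deterministic.
#'
#' @param hpc an `hpc_set`.
#' @param alignments output of [all_pairs_align()].
#' @param masks mask intervals from [mask_reads()] (may be empty).
#' @param min_support_ratio majority/own-symbol support ratio (default 4).
#' @param min_depth minimum majority support (default 4).
#' @param band alignment band half-width (default 12).
#' @param max_partners pileup partner cap per read; the longest-overlap
#'   alignments are used (default 25 — far above `min_depth`, so capping
#'   does not change the majority calls, only the work).
#' @param mask_ratio super-majority ratio for masked columns (default
#'   `2 * min_support_ratio`; 0 disables corrections inside masks).
#' @return a corrected `hpc_set` (run lengths carried through; inserted
#'   bases get run length 1).
#' @export
correct_reads <- function(hpc, alignments, masks = NULL,
                          min_support_ratio = 4, min_depth = 4L, band = 12L,
                          max_partners = 25L,
                          mask_ratio = 2 * min_support_ratio) {
  n <- length(hpc$id)
  if (nrow(alignments) > 0) {
    bad <- !(alignments$a_idx %in% seq_len(n)) |
      !(alignments$b_idx %in% seq_len(n))
    if (any(bad)) stop("alignment references unknown read")
  }
  lens <- nchar(hpc$bases)
  rc_cache <- new.env(parent = emptyenv())
  get_rc <- function(i) {
    key <- as.character(i)
    if (is.null(rc_cache[[key]])) rc_cache[[key]] <- revcomp(hpc$bases[i])
    rc_cache[[key]]
  }
  out_bases <- character(n)
  out_runs <- vector("list", n)
  # pre-split alignment row indices by read for speed
  rows_a <- split(seq_len(nrow(alignments)), alignments$a_idx)
  rows_b <- split(seq_len(nrow(alignments)), alignments$b_idx)
  for (t in seq_len(n)) {
    qa <- alignments[rows_a[[as.character(t)]] %||% integer(0), , drop = FALSE]
    qb <- alignments[rows_b[[as.character(t)]] %||% integer(0), , drop = FALSE]
    if (nrow(qa) + nrow(qb) > max_partners) {
      # keep the longest overlaps
      lens_all <- c(qa$len, qb$len)
      keep <- rank(-lens_all, ties.method = "first") <= max_partners
      na0 <- nrow(qa)
      qa <- qa[keep[seq_len(na0)], , drop = FALSE]
      qb <- qb[keep[na0 + seq_len(nrow(qb))], , drop = FALSE]
    }
    queries <- character(0)
    diags <- integer(0)
    if (nrow(qa) > 0) {
      queries <- c(queries, vapply(seq_len(nrow(qa)), function(j) {
        if (qa$strand[j] == "+") hpc$bases[qa$b_idx[j]] else get_rc(qa$b_idx[j])
      }, character(1)))
      diags <- c(diags, qa$diag)
    }
    if (nrow(qb) > 0) {
      # re-express each alignment with read t as the target
      queries <- c(queries, vapply(seq_len(nrow(qb)), function(j) {
        if (qb$strand[j] == "+") hpc$bases[qb$a_idx[j]] else get_rc(qb$a_idx[j])
      }, character(1)))
      d2 <- ifelse(qb$strand == "+", -qb$diag,
                   qb$diag - lens[qb$a_idx] + lens[t])
      diags <- c(diags, as.integer(d2))
    }
    mseg <- if (is.null(masks)) NULL else
      masks[masks$seq_id == hpc$id[t], , drop = FALSE]
    mvec <- intervals_to_mask(mseg, lens[t])
    if (length(queries) == 0) {
      out_bases[t] <- hpc$bases[t]
      out_runs[[t]] <- hpc$runs[[t]]
      next
    }
    cr <- cpp_correct_read(hpc$bases[t], queries, diags, band, mvec,
                           as.integer(min_depth), min_support_ratio,
                           mask_ratio)
    runs <- rep(1L, length(cr$src))
    kept <- cr$src >= 0L
    runs[kept] <- hpc$runs[[t]][cr$src[kept] + 1L]
    norm <- hpc_renormalize(cr$bases, as.integer(runs))
    out_bases[t] <- norm$bases
    out_runs[[t]] <- norm$runs
  }
  structure(list(id = hpc$id, bases = out_bases, runs = out_runs,
                 meta = hpc$meta), class = "hpc_set")
}

#' Exact suffix-prefix overlaps of corrected reads
#'
#' Finds all suffix-prefix matches of length at least `min_overlap` that are
#' exact outside masked positions (masked positions act as wildcards on
#' either read). Containments are flagged and excluded from graph edges by
#' [build_graph()], but retained for depth computation.
#'
#' Dovetail rows are directed: the suffix of `from` in orientation
#' `from_orient` equals the prefix of `to` in orientation `to_orient` over
#' `len` compressed bases. Coordinate columns give the overlap interval on
#' each read's forward strand. The orientation-flipped counterpart of each
#' overlap is implied; see [flip_overlap()].
#'
#' @param hpc corrected `hpc_set`.
#' @param masks mask intervals (see [mask_reads()]).
#' @param min_overlap minimum overlap length (compressed bases).
#' @param k,w,max_occ,min_seeds seeding parameters as in
#'   [all_pairs_align()].
#' @return data.frame with columns `from`, `to`, `from_idx`, `to_idx`,
#'   `from_orient`, `to_orient`, `len`, `exact`, `contained` (NA for
#'   dovetails; for containments, the id of the contained read), plus
#'   forward-strand coordinates `from_start`, `from_end`, `to_start`,
#'   `to_end`, and `diag`/`strand` in the canonical a<b frame.
#' @export
exact_overlaps <- function(hpc, masks = NULL, min_overlap = 500L, k = 21L,
                           w = 50L, max_occ = 400L, min_seeds = 1L) {
  lens <- nchar(hpc$bases)
  n <- length(hpc$id)
  seeds <- read_seeds(hpc$bases, k, w)
  cand <- pair_candidates(seeds, lens, k, max_occ, min_seeds, diag_tol = 0L)
  empty <- data.frame(from = character(0), to = character(0),
                      from_idx = integer(0), to_idx = integer(0),
                      from_orient = character(0), to_orient = character(0),
                      len = integer(0), exact = logical(0),
                      contained = character(0), from_start = integer(0),
                      from_end = integer(0), to_start = integer(0),
                      to_end = integer(0), stringsAsFactors = FALSE)
  if (nrow(cand) == 0) return(empty)
  rc_cache <- new.env(parent = emptyenv())
  get_rc <- function(i) {
    key <- as.character(i)
    if (is.null(rc_cache[[key]])) rc_cache[[key]] <- revcomp(hpc$bases[i])
    rc_cache[[key]]
  }
  mask_cache <- lapply(seq_len(n), function(i) {
    mseg <- if (is.null(masks)) NULL else
      masks[masks$seq_id == hpc$id[i], , drop = FALSE]
    intervals_to_mask(mseg, lens[i])
  })
  nc <- nrow(cand)
  keep <- logical(nc)
  from_i <- integer(nc); to_i <- integer(nc)
  from_or <- character(nc); to_or <- character(nc)
  len_v <- integer(nc); cont <- rep(NA_character_, nc)
  fs_v <- integer(nc); fe_v <- integer(nc); ts_v <- integer(nc); te_v <- integer(nc)
  for (r in seq_len(nc)) {
    ai <- cand$a[r]; bi <- cand$b[r]
    strand <- cand$strand[r]; d <- cand$diag[r]
    la <- lens[ai]; lb <- lens[bi]
    bseq <- if (strand == "+") hpc$bases[bi] else get_rc(bi)
    mb <- mask_cache[[bi]]
    if (strand == "-") mb <- rev(mb)
    ok <- cpp_check_dovetail(hpc$bases[ai], bseq, mask_cache[[ai]], mb, d)
    if (!ok) next
    ovl <- min(la - max(0L, d), lb - max(0L, -d))
    is_contain <- (d >= 0L && d + lb <= la) || (d <= 0L && la <= lb + d)
    # containments carry no graph edge, only depth: a fixed small floor
    if (ovl < (if (is_contain) min(min_overlap, 500L) else min_overlap)) next
    keep[r] <- TRUE
    if (d >= 0L && d + lb <= la) {
      # b contained in a
      from_i[r] <- ai; to_i[r] <- bi; from_or[r] <- "+"; to_or[r] <- strand
      len_v[r] <- lb; cont[r] <- hpc$id[bi]
      fs_v[r] <- d; fe_v[r] <- d + lb; ts_v[r] <- 0L; te_v[r] <- lb
    } else if (d <= 0L && la <= lb + d) {
      # a contained in b (includes identical reads)
      fs <- if (strand == "+") -d else lb + d - la  # on b's forward strand
      from_i[r] <- bi; to_i[r] <- ai; from_or[r] <- strand; to_or[r] <- "+"
      len_v[r] <- la; cont[r] <- hpc$id[ai]
      fs_v[r] <- fs; fe_v[r] <- fs + la; ts_v[r] <- 0L; te_v[r] <- la
    } else if (d > 0L) {
      # suffix of a+ matches prefix of oriented b
      L <- la - d
      ts <- if (strand == "+") 0L else lb - L
      from_i[r] <- ai; to_i[r] <- bi; from_or[r] <- "+"; to_or[r] <- strand
      len_v[r] <- L
      fs_v[r] <- d; fe_v[r] <- la; ts_v[r] <- ts; te_v[r] <- ts + L
    } else {
      # suffix of oriented b matches prefix of a+
      L <- lb + d
      fs <- if (strand == "+") -d else 0L
      from_i[r] <- bi; to_i[r] <- ai; from_or[r] <- strand; to_or[r] <- "+"
      len_v[r] <- L
      fs_v[r] <- fs; fe_v[r] <- fs + L; ts_v[r] <- 0L; te_v[r] <- L
    }
  }
  if (!any(keep)) return(empty)
  out <- data.frame(from = hpc$id[from_i[keep]], to = hpc$id[to_i[keep]],
                    from_idx = from_i[keep], to_idx = to_i[keep],
                    from_orient = from_or[keep], to_orient = to_or[keep],
                    len = len_v[keep], exact = TRUE, contained = cont[keep],
                    from_start = fs_v[keep], from_end = fe_v[keep],
                    to_start = ts_v[keep], to_end = te_v[keep],
                    strand = cand$strand[keep], diag = cand$diag[keep],
                    a_idx = cand$a[keep], b_idx = cand$b[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Orientation-flipped counterpart of dovetail overlaps
#'
#' Every suffix-prefix overlap `from^o1 -> to^o2` has a mirror
#' `to^flip(o2) -> from^flip(o1)` on the opposite strands. Containment rows
#' are returned unchanged.
#'
#' @param overlaps data.frame as returned by [exact_overlaps()].
#' @return data.frame of the flipped overlaps.
#' @export
flip_overlap <- function(overlaps) {
  dv <- overlaps
  isdove <- is.na(dv$contained)
  flip <- function(o) ifelse(o == "+", "-", "+")
  tmp <- dv[isdove, , drop = FALSE]
  res <- tmp
  res$from <- tmp$to; res$to <- tmp$from
  res$from_idx <- tmp$to_idx; res$to_idx <- tmp$from_idx
  res$from_orient <- flip(tmp$to_orient); res$to_orient <- flip(tmp$from_orient)
  res$from_start <- tmp$to_start; res$from_end <- tmp$to_end
  res$to_start <- tmp$from_start; res$to_end <- tmp$from_end
  dv[isdove, ] <- res
  dv
}

#' Write overlaps as PAF-like TSV
#'
#' @param overlaps data.frame from [exact_overlaps()] or
#'   [all_pairs_align()].
#' @param path output path.
#' @export
write_overlaps <- function(overlaps, path) {
  write.table(overlaps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
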