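# Assembly validation toolkit: summary statistics (NG50 etc.), coverage
# uniformity screening, unique k-mer marker maps and marker-assisted read
# assignment, primary/secondary allele ratios, windowed identity profiles,
# and the merged issue catalog.

#' Assembly summary statistics
#'
#' Contigs are the maximal runs between N-runs of length >= 3 (shorter N
#' runs stay internal); NG50 is the largest length L such that contigs of
#' length >= L sum to at least half of `genome_size`; assembled bases are
#' all non-N bases.
#'
#' @param assembly data.frame `id`, `bases` (as from [read_fasta()]).
#' @param genome_size the fixed genome size for NG50 (bases).
#' @return list with `total_nonN_bases`, `contig_count`, `ng50`,
#'   `contig_lengths`, `genome_size`.
#' @export
assembly_stats <- function(assembly, genome_size) {
  stopifnot(genome_size > 0)
  if (nrow(assembly) == 0 || all(nchar(assembly$bases) == 0))
    stop("empty assembly")
  contigs <- unlist(lapply(assembly$bases, function(s) {
    parts <- strsplit(gsub("N{3,}", "!", s), "!", fixed = TRUE)[[1]]
    parts[nchar(parts) > 0]
  }))
  clen <- nchar(contigs)
  total <- sum(nchar(gsub("N", "", assembly$bases)))
  sl <- sort(clen, decreasing = TRUE)
  cum <- cumsum(sl)
  ng50 <- if (any(cum >= genome_size / 2)) sl[which(cum >= genome_size / 2)[1]]
          else NA_integer_
  list(total_nonN_bases = total, contig_count = length(contigs),
       ng50 = ng50, contig_lengths = clen, genome_size = genome_size)
}

#' Per-position coverage profile from alignment intervals
#'
#' @param alignments data.frame with `start`, `end` (0-based half-open
#'   target intervals; a `target` column, if present, must be uniform).
#' @param target_len target sequence length.
#' @param target target id recorded on the profile.
#' @param tech technology tag.
#' @return object of class `coverage_profile`: list with `target`, `depth`
#'   (integer vector), `mean`, `sd`, `tech`.
#' @export
coverage_profile <- function(alignments, target_len, target = "target",
                             tech = "hifi") {
  d <- integer(target_len + 1L)
  if (nrow(alignments) > 0) {
    s <- pmax(0L, pmin(target_len, alignments$start))
    e <- pmax(0L, pmin(target_len, alignments$end))
    ts <- table(s); te <- table(e)
    d[as.integer(names(ts)) + 1L] <- d[as.integer(names(ts)) + 1L] + as.integer(ts)
    d[as.integer(names(te)) + 1L] <- d[as.integer(names(te)) + 1L] - as.integer(te)
  }
  depth <- cumsum(d)[seq_len(target_len)]
  structure(list(target = target, depth = depth, mean = mean(depth),
                 sd = sd(depth), tech = tech),
            class = "coverage_profile")
}

#' Flag out-of-band coverage
#'
#' The in-band region is mean +/- `n_sd` standard deviations of the
#' per-position depth. When coverage is perfectly constant (sd = 0) the
#' whole target counts as in-band. Merged out-of-band intervals become
#' issues: `low_coverage` below the band, `error` (candidate) above it.
#'
#' @param profile a `coverage_profile`, or a plain numeric per-position
#'   depth vector.
#' @param n_sd band half-width in standard deviations (default 3).
#' @return list with `fraction_in_band` (rounded to 4 decimals) and
#'   `issues` (data.frame `target`, `start`, `end`, `kind`, `evidence`).
#' @export
flag_coverage <- function(profile, n_sd = 3) {
  if (is.numeric(profile)) {
    profile <- structure(list(target = "target", depth = profile,
                              mean = mean(profile), sd = sd(profile),
                              tech = "sim"),
                         class = "coverage_profile")
  }
  depth <- profile$depth
  m <- profile$mean; s <- profile$sd
  if (is.na(s) || s == 0) {
    return(list(fraction_in_band = 1.0000,
                issues = data.frame(target = character(0), start = integer(0),
                                    end = integer(0), kind = character(0),
                                    evidence = character(0))))
  }
  lo <- m - n_sd * s; hi <- m + n_sd * s
  below <- depth < lo; above <- depth > hi
  frac <- round(mean(!below & !above), 4)
  mk <- function(flag, kind) {
    if (!any(flag)) return(NULL)
    r <- rle(flag)
    e <- cumsum(r$lengths); s0 <- e - r$lengths
    data.frame(target = profile$target, start = s0[r$values], end = e[r$values],
               kind = kind,
               evidence = sprintf("band [%.2f, %.2f], tech %s", lo, hi,
                                  profile$tech),
               stringsAsFactors = FALSE)
  }
  issues <- rbind(mk(below, "low_coverage"), mk(above, "error"))
  issues <- issues %||% data.frame(target = character(0), start = integer(0),
                                   end = integer(0), kind = character(0),
                                   evidence = character(0))
  rownames(issues) <- NULL
  list(fraction_in_band = frac, issues = issues)
}

#' Unique k-mer markers of an assembly
#'
#' Markers are canonical (strand-collapsed) k-mers occurring exactly once
#' across the whole assembly; they anchor reads unambiguously inside
#' near-identical repeats. Also returns a marker-density track.
#'
#' @param assembly data.frame `id`, `bases`, or a single string.
#' @param k marker k-mer size (>= 11; default 21).
#' @param density_window window for the density track (default 10000).
#' @return list with `markers` (data.frame `target`, `pos`, `code`) and
#'   `density` (list per target of markers-per-window counts).
#' @export
unique_markers <- function(assembly, k = 21L, density_window = 10000L) {
  stopifnot(k >= 11L)
  if (is.character(assembly)) assembly <- data.frame(id = "seq", bases = assembly,
                                                     stringsAsFactors = FALSE)
  scans <- lapply(seq_len(nrow(assembly)), function(i) {
    df <- cpp_kmer_scan(assembly$bases[i], as.integer(k), 1L)
    if (nrow(df) == 0) return(NULL)
    data.table::data.table(target = assembly$id[i], pos = df$pos, code = df$code)
  })
  dt <- data.table::rbindlist(scans)
  if (is.null(dt) || nrow(dt) == 0) {
    return(list(markers = data.frame(target = character(0), pos = integer(0),
                                     code = numeric(0)),
                density = list()))
  }
  occ <- dt[, list(nocc = .N), by = "code"]
  mk <- merge(dt, occ[occ$nocc == 1L, "code"], by = "code")
  data.table::setorder(mk, target, pos)
  markers <- as.data.frame(mk[, c("target", "pos", "code")])
  density <- lapply(seq_len(nrow(assembly)), function(i) {
    len <- nchar(assembly$bases[i])
    nw <- max(1L, ceiling(len / density_window))
    tab <- tabulate(markers$pos[markers$target == assembly$id[i]] %/%
                      density_window + 1L, nbins = nw)
    tab
  })
  names(density) <- assembly$id
  list(markers = markers, density = density)
}

#' Marker-assisted assignment of multi-mapping reads
#'
#' Each read is assigned to the candidate location whose span contains the
#' most markers that also occur in the read; reads with zero agreeing
#' markers anywhere keep their primary alignment, flagged low-confidence.
#'
#' @param candidates data.frame of candidate alignments: `read_id`,
#'   `target`, `start`, `end`, `primary` (logical).
#' @param markers marker table from [unique_markers()].
#' @param reads data.frame `id`, `bases` for k-mer membership tests.
#' @param k marker k-mer size (must match the marker set).
#' @return `candidates` with added `n_markers`, `assigned` (logical) and
#'   `low_confidence` (logical).
#' @export
marker_assign <- function(candidates, markers, reads, k = 21L) {
  mdt <- data.table::as.data.table(markers)
  read_codes <- lapply(seq_len(nrow(reads)), function(i) {
    df <- cpp_kmer_scan(reads$bases[i], as.integer(k), 1L)
    unique(df$code)
  })
  names(read_codes) <- reads$id
  candidates$n_markers <- 0L
  for (i in seq_len(nrow(candidates))) {
    cc <- candidates[i, ]
    span <- mdt[mdt$target == cc$target & mdt$pos >= cc$start &
                  mdt$pos < cc$end, ]
    rc <- read_codes[[cc$read_id]]
    if (!is.null(rc) && nrow(span) > 0)
      candidates$n_markers[i] <- sum(span$code %in% rc)
  }
  candidates$assigned <- FALSE
  candidates$low_confidence <- FALSE
  for (rid in unique(candidates$read_id)) {
    ii <- which(candidates$read_id == rid)
    best <- max(candidates$n_markers[ii])
    if (best == 0L) {
      j <- ii[which(candidates$primary[ii])[1]]
      if (is.na(j)) j <- ii[1]
      candidates$assigned[j] <- TRUE
      candidates$low_confidence[j] <- TRUE
    } else {
      j <- ii[which(candidates$n_markers[ii] == best)[1]]
      candidates$assigned[j] <- TRUE
    }
  }
  candidates
}

#' Primary/secondary allele-ratio track
#'
#' Per window, the fraction primary / (primary + most-frequent-secondary)
#' of read support; windows below `threshold` at sufficient depth are
#' flagged as heterozygous-variant (or error) candidates.
#'
#' @param pileup data.frame with `pos` (0-based), `primary` (reads
#'   supporting the assembly base) and `secondary` (reads supporting the
#'   most frequent alternative).
#' @param target_len target length.
#' @param window window size (default 1000).
#' @param threshold flagging threshold on the fraction (default 0.8).
#' @param min_depth minimum mean depth for a window to be flaggable
#'   (default 10).
#' @param target target id for issues.
#' @return list with `fraction` (per-window), `issues`.
#' @export
allele_ratio <- function(pileup, target_len, window = 1000L, threshold = 0.8,
                         min_depth = 10, target = "target") {
  nw <- max(1L, ceiling(target_len / window))
  wi <- pileup$pos %/% window + 1L
  prim <- vapply(seq_len(nw), function(w) sum(pileup$primary[wi == w]),
                 numeric(1))
  sec <- vapply(seq_len(nw), function(w) sum(pileup$secondary[wi == w]),
                numeric(1))
  npos <- vapply(seq_len(nw), function(w)
    max(1L, sum(wi == w)), numeric(1))
  frac <- ifelse(prim + sec > 0, prim / (prim + sec), 1)
  depth <- (prim + sec) / npos
  flag <- frac < threshold & depth >= min_depth
  issues <- if (any(flag)) {
    data.frame(target = target, start = (which(flag) - 1L) * window,
               end = pmin(target_len, which(flag) * window),
               kind = "het_variant",
               evidence = sprintf("primary fraction %.3f", frac[flag]),
               stringsAsFactors = FALSE)
  } else data.frame(target = character(0), start = integer(0),
                    end = integer(0), kind = character(0),
                    evidence = character(0))
  list(fraction = frac, issues = issues)
}

#' Windowed maximum-identity profile between two sequences
#'
#' For each window of `a`, the maximum alignment identity against any
#' window of `b` (candidate windows prefiltered by shared k-mer count),
#' boxcar-smoothed over `smooth / window` consecutive windows.
#'
#' @param a,b DNA strings.
#' @param window window size (default 10000).
#' @param smooth smoothing span (default 100000).
#' @param k prefilter k-mer size (default 15).
#' @param top number of candidate windows aligned per query window.
#' @return list with `identity` (per-window %, smoothed) and `raw`.
#' @export
window_identity <- function(a, b, window = 10000L, smooth = 100000L,
                            k = 15L, top = 3L) {
  la <- nchar(a); lb <- nchar(b)
  stopifnot(la > 0, lb > 0, window <= min(la, lb))
  wa <- substring(a, seq(1, la - window + 1, by = window),
                  pmin(la, seq(1, la - window + 1, by = window) + window - 1))
  wb <- substring(b, seq(1, lb - window + 1, by = window),
                  pmin(lb, seq(1, lb - window + 1, by = window) + window - 1))
  codes_b <- lapply(wb, function(s) unique(cpp_kmer_scan(s, as.integer(k), 1L)$code))
  raw <- vapply(seq_along(wa), function(i) {
    ca <- unique(cpp_kmer_scan(wa[i], as.integer(k), 1L)$code)
    shared <- vapply(codes_b, function(cb) length(intersect(ca, cb)), integer(1))
    cand <- order(shared, decreasing = TRUE)[seq_len(min(top, length(wb)))]
    max(vapply(cand, function(j)
      seq_identity(wa[i], wb[j], band = max(64L, ceiling(0.3 * window))),
      numeric(1)))
  }, numeric(1))
  span <- max(1L, round(smooth / window))
  sm <- as.numeric(stats::filter(raw, rep(1 / span, span), sides = 2))
  sm[is.na(sm)] <- raw[is.na(sm)]
  list(identity = sm, raw = raw)
}

#' Merge an issue list into a catalog with an affected-fraction summary
#'
#' Overlapping issues are merged per kind; the summary reports affected
#' bases and the percentage of the assembly length.
#'
#' @param issues data.frame with `target`, `start`, `end`, `kind`.
#' @param assembly_len total assembly length (bases).
#' @return list with `catalog` (merged intervals), `affected_bases`,
#'   `affected_pct` (4 decimals).
#' @export
issue_catalog <- function(issues, assembly_len) {
  if (nrow(issues) == 0) {
    return(list(catalog = issues, affected_bases = 0L, affected_pct = 0))
  }
  parts <- split(issues, paste(issues$target, issues$kind))
  catalog <- do.call(rbind, lapply(parts, merge_intervals))
  rownames(catalog) <- NULL
  merged_all <- do.call(rbind, lapply(split(issues, issues$target),
                                      function(d)
                                        merge_intervals(d[, c("start", "end")])))
  affected <- sum(merged_all$end - merged_all$start)
  list(catalog = catalog,
       affected_bases = affected,
       affected_pct = round(100 * affected / assembly_len, 4))
}
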