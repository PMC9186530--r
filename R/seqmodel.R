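# Core sequence model: FASTA/FASTQ I/O, homopolymer compression with a
# bidirectional coordinate map, and simple-sequence-repeat (microsatellite)
# detection and masking.
#
# Conventions: all coordinates are 0-based half-open (BED-compatible);
# strands are "+"/"-"; sequences are plain uppercase strings over ACGTN.

#' Read a FASTA file into a sequence table
#'
#' Sequences are uppercased on ingest and validated against the ACGTN
#' alphabet. Multi-line records are concatenated.
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns `id`, `bases`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  out <- data.frame(id = sub("\\s.*$", "", names(ss)),
                    bases = toupper(as.character(ss)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  bad <- grepl("[^ACGTN]", out$bases)
  if (any(bad)) {
    stop("illegal character in record '", out$id[which(bad)[1]], "'")
  }
  out
}

#' Write a sequence table to FASTA
#'
#' @param seqs data.frame with columns `id`, `bases`.
#' @param path output path.
#' @param width line wrap width (default 80 columns).
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  ss <- Biostrings::DNAStringSet(seqs$bases)
  names(ss) <- seqs$id
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a FASTQ file (qualities parsed but dropped)
#'
#' @param path path to a FASTQ file.
#' @return data.frame with columns `id`, `bases`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = sub("\\s.*$", "", names(ss)),
             bases = toupper(as.character(ss)),
             stringsAsFactors = FALSE)
}

#' Homopolymer-compress a sequence
#'
#' Collapses each run of identical bases to a single base, recording run
#' lengths so that the transform is invertible and coordinates can be mapped
#' in both directions. This neutralises the dominant error mode of accurate
#' long reads (homopolymer-length indels). N runs are compressed like any
#' other base.
#'
#' @param bases a single DNA string.
#' @param id origin sequence id (stored on the result).
#' @return an object of class `hpc_seq`: list with `bases` (compressed
#'   string, no two equal adjacent characters), `run_lengths` (integer
#'   vector, one per compressed base) and `origin_id`.
#' @export
hpc_compress <- function(bases, id = "") {
  if (nchar(bases) == 0) {
    return(structure(list(bases = "", run_lengths = integer(0), origin_id = id),
                     class = "hpc_seq"))
  }
  r <- rle(strsplit(bases, "", fixed = TRUE)[[1]])
  structure(list(bases = paste(r$values, collapse = ""),
                 run_lengths = as.integer(r$lengths),
                 origin_id = id),
            class = "hpc_seq")
}

#' Decompress a homopolymer-compressed sequence
#'
#' Exact inverse of [hpc_compress()].
#'
#' @param h an `hpc_seq`.
#' @return the original DNA string.
#' @export
hpc_decompress <- function(h) {
  if (any(h$run_lengths < 1L)) stop("run length < 1")
  if (nchar(h$bases) == 0) return("")
  paste(strrep(strsplit(h$bases, "", fixed = TRUE)[[1]], h$run_lengths),
        collapse = "")
}

#' Map a coordinate between compressed and original space
#'
#' `to_compressed` maps an original-space position to the index of the run
#' containing it; `to_original` maps a compressed index to the original-space
#' start of its run. Both directions are monotone non-decreasing, and
#' composing them lands within the run containing the starting position.
#'
#' @param h an `hpc_seq`.
#' @param pos 0-based position(s) in the source space.
#' @param direction `"to_compressed"` or `"to_original"`.
#' @return integer vector of mapped 0-based positions.
#' @export
map_coordinate <- function(h, pos, direction = c("to_compressed", "to_original")) {
  direction <- match.arg(direction)
  n <- length(h$run_lengths)
  starts <- c(0L, cumsum(h$run_lengths)) # length n+1; starts[i] = orig start of run i-1
  if (direction == "to_compressed") {
    total <- starts[n + 1L]
    if (any(pos < 0L | pos >= total)) stop("position out of range")
    findInterval(pos, starts[seq_len(n)]) - 1L
  } else {
    if (any(pos < 0L | pos >= n)) stop("position out of range")
    starts[pos + 1L]
  }
}

# merge equal adjacent bases (can arise after correction edits), summing runs
hpc_renormalize <- function(bases, runs) {
  if (nchar(bases) <= 1) return(list(bases = bases, runs = runs))
  ch <- strsplit(bases, "", fixed = TRUE)[[1]]
  grp <- cumsum(c(TRUE, ch[-1] != ch[-length(ch)]))
  if (max(grp) == length(ch)) return(list(bases = bases, runs = runs))
  list(bases = paste(ch[!duplicated(grp)], collapse = ""),
       runs = as.integer(tapply(runs, grp, sum)))
}

#' Detect perfect microsatellites (simple sequence repeats)
#'
#' Finds maximal perfect tandem repetitions of units with period 1 to
#' `max_unit`, keeping those of total length at least `min_length` with at
#' least `min_copies` copies. Overlapping intervals (across periods) are
#' merged; the unit of the longest contributing interval is kept. Runs of N
#' are always masked.
#'
#' @param bases a single DNA string.
#' @param max_unit maximum repeat unit period (default 6).
#' @param min_length minimum total repeat tract length (default 10).
#' @param min_copies minimum number of unit copies (default 3).
#' @param seq_id id recorded on the returned intervals.
#' @return data.frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open), `unit`; sorted and non-overlapping.
#' @export
find_microsatellites <- function(bases, max_unit = 6L, min_length = 10L,
                                 min_copies = 3L, seq_id = "") {
  n <- nchar(bases)
  empty <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), unit = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  tr <- cpp_perfect_tandems(bases, as.integer(max_unit),
                            as.integer(min_length), min_copies)
  df <- NULL
  if (nrow(tr) > 0) {
    df <- data.frame(seq_id = seq_id, start = tr$start, end = tr$end,
                     unit = substring(bases, tr$start + 1L,
                                      tr$start + tr$period),
                     stringsAsFactors = FALSE)
  }
  # N runs always masked
  nr <- gregexpr("N+", bases)[[1]]
  if (nr[1] != -1) {
    df <- rbind(df, data.frame(
      seq_id = seq_id, start = as.integer(nr) - 1L,
      end = as.integer(nr) - 1L + attr(nr, "match.length"), unit = "N",
      stringsAsFactors = FALSE))
  }
  if (is.null(df) || nrow(df) == 0) return(empty)
  # keep the longest interval's unit on merge
  df <- df[order(df$start, -(df$end - df$start)), , drop = FALSE]
  out <- merge_intervals(df)
  rownames(out) <- NULL
  out
}

#' Microsatellite density per window
#'
#' Fraction of masked bases per fixed-size window; the last partial window is
#' normalised by its own length.
#'
#' @param bases a single DNA string (or NULL if `len` given).
#' @param window window size in bases (default 128).
#' @param intervals optional precomputed mask intervals (as from
#'   [find_microsatellites()]); computed from `bases` if missing.
#' @param len sequence length; inferred from `bases` if missing.
#' @param ... passed to [find_microsatellites()].
#' @return numeric vector of per-window masked fractions in \[0, 1\].
#' @export
microsat_density <- function(bases = NULL, window = 128L, intervals = NULL,
                             len = NULL, ...) {
  stopifnot(window >= 1L)
  if (is.null(len)) len <- nchar(bases)
  if (is.null(intervals)) intervals <- find_microsatellites(bases, ...)
  mask <- intervals_to_mask(intervals, len)
  nw <- ceiling(len / window)
  vapply(seq_len(nw), function(i) {
    s <- (i - 1L) * window + 1L
    e <- min(len, i * window)
    mean(mask[s:e])
  }, numeric(1))
}

#' Export mask or issue intervals as BED
#'
#' @param intervals data.frame with `seq_id` (or `target`), `start`, `end`
#'   and optionally a name-like column (`unit` or `kind`).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  id <- intervals$seq_id %||% intervals$target
  name <- intervals$unit %||% (intervals$kind %||% rep(".", nrow(intervals)))
  df <- data.frame(id, intervals$start, intervals$end, name)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
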