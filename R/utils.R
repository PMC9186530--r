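# Shared internal helpers: reverse complement, seeded RNG scoping, interval
# arithmetic (0-based half-open throughout, BED-compatible).

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character strings (alphabet
#' ACGTN).
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  cpp_revcomp(as.character(x))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Merge overlapping/adjacent 0-based half-open intervals. df: start, end
# (plus arbitrary other columns; first row's values kept on merge).
merge_intervals <- function(df, gap = 0L) {
  if (is.null(df) || nrow(df) == 0) return(df)
  df <- df[order(df$start, df$end), , drop = FALSE]
  keep <- integer(0)
  cur <- 1L
  cur_end <- df$end[1]
  for (i in seq_len(nrow(df))[-1]) {
    if (df$start[i] <= cur_end + gap) {
      cur_end <- max(cur_end, df$end[i])
    } else {
      df$end[cur] <- cur_end
      keep <- c(keep, cur)
      cur <- i
      cur_end <- df$end[i]
    }
  }
  df$end[cur] <- cur_end
  keep <- c(keep, cur)
  df[keep, , drop = FALSE]
}

# Total bases covered by a set of (already merged or unmerged) intervals.
interval_bases <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(0L)
  m <- merge_intervals(df[, c("start", "end"), drop = FALSE])
  sum(m$end - m$start)
}

# logical mask vector of length len from interval data.frame
intervals_to_mask <- function(df, len) {
  m <- logical(len)
  if (!is.null(df) && nrow(df) > 0) {
    for (i in seq_len(nrow(df))) {
      s <- max(0L, df$start[i])
      e <- min(len, df$end[i])
      if (e > s) m[(s + 1L):e] <- TRUE
    }
  }
  m
}

# mode of an integer vector with smaller-value tie-break
int_mode_min <- function(x) {
  t <- table(x)
  v <- as.integer(names(t))
  min(v[t == max(t)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
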