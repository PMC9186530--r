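# Synthetic genome and read simulator. Provides ground truth for every
# other module: repeat structures with tunable identity, satellite-like
# arrays, an rDNA-like morph array, homopolymer-dense and GA-rich tracts,
# and two read technologies (accurate ~20 kbp "HiFi-like" reads whose errors
# are mostly homopolymer-length indels, and noisy >=100 kbp "ONT-like"
# reads). All outputs are exactly reproducible from (spec, seed).

#' Build a genome specification
#'
#' Describes a haploid genome for [simulate_genome()]. All lengths are in
#' bases; identities are fractions in (0, 1].
#'
#' @param seed RNG seed; every simulator output is a deterministic function
#'   of the spec (which includes this seed).
#' @param backbone_len integer vector of chromosome backbone lengths.
#' @param repeats list of repeat families; each element a list with `length`,
#'   `copies`, `identity` (pairwise identity of the copies to the family
#'   consensus) and optionally `placement`, a data.frame with columns `chrom`
#'   (1-based index) and `pos` (0-based backbone offset); random non-
#'   overlapping placement on chromosome 1 if omitted.
#' @param satellites list of satellite arrays: `unit` (string or unit
#'   length), `copies`, `divergence` (per-copy mutation fraction), optional
#'   `chrom`/`pos`.
#' @param rdna NULL or a list describing an rDNA-like tandem array: `unit_len`,
#'   `morphs` (number of distinct morphs), `identity` (pairwise identity
#'   between morphs), `copy_numbers` (integer vector, one per morph),
#'   `arrangement` ("shuffled" or "blocks"), optional `chrom`/`pos`.
#' @param homopolymer_boost rate (expected events per base) at which backbone
#'   positions are expanded into homopolymer runs of length 4-12.
#' @param ga_tracts list of GA-rich tracts: each a list with `chrom`, `pos`,
#'   `length`.
#' @return object of class `genome_spec`.
#' @export
genome_spec <- function(seed = 1L, backbone_len = 200000L, repeats = list(),
                        satellites = list(), rdna = NULL,
                        homopolymer_boost = 0, ga_tracts = list()) {
  stopifnot(all(backbone_len > 0))
  structure(list(seed = as.integer(seed), backbone_len = as.integer(backbone_len),
                 repeats = repeats, satellites = satellites, rdna = rdna,
                 homopolymer_boost = homopolymer_boost, ga_tracts = ga_tracts),
            class = "genome_spec")
}

random_dna <- function(n, prob = NULL) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# point-mutate a string to exactly the requested identity (the divergence
# of a repeat copy or morph is a specified study condition, not noise, so
# the substitution count is deterministic; positions remain random)
mutate_identity <- function(bases, identity) {
  n <- nchar(bases)
  k <- round(n * (1 - identity))
  if (k == 0) return(bases)
  ch <- strsplit(bases, "", fixed = TRUE)[[1]]
  idx <- sample.int(n, k)
  for (i in idx) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  paste(ch, collapse = "")
}

#' Simulate a genome from a specification
#'
#' Repeat copies are diverged from a family consensus by uniform point
#' mutation to the specified identity and substituted into the backbone at
#' non-overlapping positions. The rDNA-like array is a tandem of morph units
#' with the given copy numbers, either shuffled or in blocks; its true unit
#' order is recorded. GA-rich tracts replace backbone sequence with
#' GA-biased sequence (emulating coverage dropout of accurate reads there).
#'
#' @param spec a [genome_spec()].
#' @return list with `genome` (data.frame `id`, `bases`) and `truth`, a list
#'   with `placements` (feature table: chrom, start, end, kind, family,
#'   copy), `rdna_order` (true morph order, or NULL), `morphs` (morph
#'   consensus table, or NULL) and `ga_tracts`.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    chroms <- lapply(spec$backbone_len, function(n) {
      s <- random_dna(n)
      if (spec$homopolymer_boost > 0) {
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        k <- rbinom(1, n, spec$homopolymer_boost)
        if (k > 0) {
          idx <- sort(sample.int(n, k))
          ch[idx] <- strrep(ch[idx], sample(4:12, k, replace = TRUE))
          s <- paste(ch, collapse = "")
        }
      }
      s
    })
    placements <- list()
    used <- lapply(seq_along(chroms), function(i) data.frame(start = integer(0), end = integer(0)))
    place <- function(chrom, pos, len) {
      # find a non-overlapping slot; pos NULL -> random on given chrom
      n <- nchar(chroms[[chrom]])
      if (is.null(pos)) {
        for (try in 1:200) {
          p <- sample.int(n - len, 1) - 1L
          u <- used[[chrom]]
          if (!any(p < u$end + 500 & p + len + 500 > u$start)) {
            return(p)
          }
        }
        stop("infeasible placement: no free slot of length ", len)
      }
      if (pos + len > n) stop("infeasible placement: position ", pos,
                              " + length ", len, " exceeds chromosome ", chrom)
      pos
    }
    paste_in <- function(chrom, pos, seqs) {
      # substitute (not insert) seqs at pos, keeping backbone length fixed
      s <- chroms[[chrom]]
      ins <- paste(seqs, collapse = "")
      stopifnot(pos + nchar(ins) <= nchar(s))
      chroms[[chrom]] <<- paste0(substr(s, 1, pos),
                                 ins,
                                 substr(s, pos + nchar(ins) + 1, nchar(s)))
      used[[chrom]] <<- rbind(used[[chrom]],
                              data.frame(start = pos, end = pos + nchar(ins)))
    }
    ri <- 0L
    for (rep_fam in spec$repeats) {
      ri <- ri + 1L
      fam <- sprintf("repeat%d", ri)
      consensus <- random_dna(rep_fam$length)
      pl <- rep_fam$placement
      for (ci in seq_len(rep_fam$copies)) {
        copy <- mutate_identity(consensus, rep_fam$identity %||% 1)
        chrom <- if (!is.null(pl)) pl$chrom[ci] else 1L
        pos <- place(chrom, if (!is.null(pl)) pl$pos[ci] else NULL, nchar(copy))
        paste_in(chrom, pos, copy)
        placements[[length(placements) + 1L]] <- data.frame(
          chrom = chrom, start = pos, end = pos + nchar(copy),
          kind = "repeat", family = fam, copy = ci, stringsAsFactors = FALSE)
      }
    }
    si <- 0L
    for (sat in spec$satellites) {
      si <- si + 1L
      unit <- if (is.character(sat$unit)) sat$unit else random_dna(sat$unit)
      copies <- vapply(seq_len(sat$copies), function(i)
        mutate_identity(unit, 1 - (sat$divergence %||% 0)), character(1))
      len <- sum(nchar(copies))
      chrom <- sat$chrom %||% 1L
      pos <- place(chrom, sat$pos, len)
      paste_in(chrom, pos, copies)
      placements[[length(placements) + 1L]] <- data.frame(
        chrom = chrom, start = pos, end = pos + len,
        kind = "satellite", family = sprintf("sat%d", si), copy = NA_integer_,
        stringsAsFactors = FALSE)
    }
    rdna_order <- NULL
    morph_tab <- NULL
    if (!is.null(spec$rdna)) {
      rd <- spec$rdna
      base_unit <- random_dna(rd$unit_len)
      morphs <- vapply(seq_len(rd$morphs), function(i)
        if (i == 1) base_unit else mutate_identity(base_unit, rd$identity),
        character(1))
      cn <- rd$copy_numbers
      stopifnot(length(cn) == rd$morphs)
      order_idx <- rep(seq_len(rd$morphs), cn)
      if ((rd$arrangement %||% "shuffled") == "shuffled") {
        order_idx <- sample(order_idx)
      }
      units <- morphs[order_idx]
      chrom <- rd$chrom %||% 1L
      pos <- place(chrom, rd$pos, sum(nchar(units)))
      paste_in(chrom, pos, units)
      off <- pos + c(0L, cumsum(nchar(units)))
      for (ui in seq_along(units)) {
        placements[[length(placements) + 1L]] <- data.frame(
          chrom = chrom, start = off[ui], end = off[ui + 1L],
          kind = "rdna_unit", family = sprintf("morph%d", order_idx[ui]),
          copy = ui, stringsAsFactors = FALSE)
      }
      rdna_order <- order_idx
      morph_tab <- data.frame(morph = sprintf("morph%d", seq_len(rd$morphs)),
                              bases = morphs, copy_number = cn,
                              stringsAsFactors = FALSE)
    }
    ga <- list()
    for (tr in spec$ga_tracts) {
      chrom <- tr$chrom %||% 1L
      gaseq <- random_dna(tr$length, prob = c(0.45, 0.04, 0.47, 0.04))
      paste_in(chrom, tr$pos, gaseq)
      ga[[length(ga) + 1L]] <- data.frame(chrom = chrom, start = tr$pos,
                                          end = tr$pos + tr$length)
    }
    genome <- data.frame(id = sprintf("chr%d", seq_along(chroms)),
                         bases = unlist(chroms), stringsAsFactors = FALSE)
    truth <- list(
      placements = if (length(placements)) do.call(rbind, placements) else NULL,
      rdna_order = rdna_order, morphs = morph_tab,
      ga_tracts = if (length(ga)) do.call(rbind, ga) else NULL)
    list(genome = genome, truth = truth)
  })
}

# apply sequencing errors to one read; returns mutated string.
# HiFi mode: `hp_frac` of errors are homopolymer-length +/-1 indels targeted
# at existing runs; the rest are substitutions. ONT mode: 50% substitution,
# 25% insertion, 25% deletion.
apply_errors <- function(bases, error_rate, mode = c("hifi", "ont"),
                         hp_frac = 0.8) {
  mode <- match.arg(mode)
  n <- nchar(bases)
  k <- rbinom(1, n, error_rate)
  if (k == 0) return(bases)
  ch <- strsplit(bases, "", fixed = TRUE)[[1]]
  # out[i]: replacement string for position i
  out <- ch
  if (mode == "hifi") {
    n_hp <- rbinom(1, k, hp_frac)
    n_sub <- k - n_hp
    if (n_hp > 0) {
      # target positions inside homopolymer runs where possible
      r <- rle(ch)
      runpos <- cumsum(r$lengths) - r$lengths + 1L # run starts
      long <- which(r$lengths >= 2)
      pick_from <- if (length(long) > 0) runpos[long] else seq_len(n)
      idx <- sample(pick_from, n_hp, replace = TRUE)
      for (i in idx) {
        if (runif(1) < 0.5) out[i] <- strrep(ch[i], 2) # +1 insertion
        else out[i] <- "" # -1 deletion
      }
    }
    if (n_sub > 0) {
      idx <- sample.int(n, n_sub)
      for (i in idx) out[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    }
  } else {
    idx <- sample.int(n, k)
    kinds <- sample(c("sub", "ins", "del"), k, replace = TRUE,
                    prob = c(0.5, 0.25, 0.25))
    for (j in seq_len(k)) {
      i <- idx[j]
      if (kinds[j] == "sub") out[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
      else if (kinds[j] == "ins") out[i] <- paste0(ch[i], sample(c("A", "C", "G", "T"), 1))
      else out[i] <- ""
    }
  }
  paste(out, collapse = "")
}

# shared read sampler: draws reads until total bases reach depth * genome
# length; starts may overhang ends and are clipped, so terminal coverage is
# uniform. Suppresses reads crossing `avoid` tracts with prob `avoid_prob`.
sample_reads <- function(genome, depth, draw_len, tech, error_rate, mode,
                         min_len = 500L, avoid = NULL, avoid_prob = 0.98,
                         prefix = tech) {
  total_target <- depth * sum(nchar(genome$bases))
  glen <- nchar(genome$bases)
  reads <- list()
  got <- 0
  i <- 0L
  guard <- 0L
  guard_max <- 200 * (total_target / max(min_len, 1)) + 10000
  while (got < total_target) {
    guard <- guard + 1L
    if (guard > guard_max) stop("read sampling failed to reach target depth")
    len <- max(min_len, round(draw_len(1)))
    chrom <- sample.int(nrow(genome), 1, prob = glen)
    g <- glen[chrom]
    s <- sample.int(g + len - 1L, 1) - len # in [-len+1, g-1]
    e <- min(g, s + len)
    s <- max(0L, s)
    if (e - s < min_len) next
    if (!is.null(avoid)) {
      tr <- avoid[avoid$chrom == chrom, , drop = FALSE]
      if (nrow(tr) > 0 && any(s < tr$end & e > tr$start) &&
          runif(1) < avoid_prob) next
    }
    i <- i + 1L
    raw <- substr(genome$bases[chrom], s + 1L, e)
    mut <- apply_errors(raw, error_rate, mode)
    strand <- sample(c("+", "-"), 1)
    if (strand == "-") mut <- revcomp(mut)
    reads[[i]] <- data.frame(
      id = sprintf("%s_%06d", prefix, i), bases = mut, tech = tech,
      truth_chrom = genome$id[chrom], truth_start = s, truth_end = e,
      truth_strand = strand, stringsAsFactors = FALSE)
    got <- got + (e - s)
  }
  out <- do.call(rbind, reads)
  rownames(out) <- NULL
  out
}

#' Simulate HiFi-like reads
#'
#' Accurate ~20 kbp reads at ~0.1% error, with errors predominantly (80%)
#' homopolymer-length +/-1 indels and the remainder substitutions. Read
#' lengths are Normal(mean_len, 0.1 mean_len) truncated below; reads are
#' drawn until the requested depth is reached, and start points overhang the
#' chromosome ends (clipped) so that terminal coverage is uniform. When
#' `ga_dropout` tracts are supplied, reads whose span would cross a tract
#' are suppressed with high probability, emulating coverage dropout over
#' GA-rich sequence.
#'
#' @param genome data.frame `id`, `bases` (as from [simulate_genome()]).
#' @param depth target mean coverage depth.
#' @param mean_len mean read length (default 20000).
#' @param error_rate per-base error rate (default 0.001).
#' @param ga_dropout NULL, or a data.frame of tracts (`chrom`, `start`,
#'   `end`) to deplete (e.g. `truth$ga_tracts`).
#' @param seed RNG seed.
#' @return read table: `id`, `bases`, `tech`, and truth columns
#'   `truth_chrom`, `truth_start`, `truth_end` (0-based half-open),
#'   `truth_strand`.
#' @export
simulate_hifi <- function(genome, depth, mean_len = 20000, error_rate = 0.001,
                          ga_dropout = NULL, seed = 1L) {
  stopifnot(depth > 0)
  with_seed(seed, {
    draw <- function(n) pmax(0.2 * mean_len, rnorm(n, mean_len, 0.1 * mean_len))
    sample_reads(genome, depth, draw, "hifi", error_rate, "hifi",
                 min_len = min(500L, floor(0.2 * mean_len)),
                 avoid = ga_dropout)
  })
}

#' Simulate ONT-like ultra-long reads
#'
#' Noisy (default 5% error: 50% substitutions, 25% insertions, 25%
#' deletions) reads with heavy-tailed (lognormal) lengths around
#' `mean_len`.
#'
#' @inheritParams simulate_hifi
#' @param mean_len mean read length (default 100000).
#' @param error_rate per-base error rate (default 0.05).
#' @return read table as for [simulate_hifi()], `tech = "ont"`.
#' @export
simulate_ont <- function(genome, depth, mean_len = 100000, error_rate = 0.05,
                         seed = 1L) {
  stopifnot(depth > 0)
  with_seed(seed, {
    sdlog <- 0.5
    mulog <- log(mean_len) - sdlog^2 / 2
    draw <- function(n) rlnorm(n, mulog, sdlog)
    sample_reads(genome, depth, draw, "ont", error_rate, "ont",
                 min_len = 1000L)
  })
}

#' Simulate Illumina-like short reads (for depth-based copy estimates)
#'
#' Error-free fixed-length short reads at the requested depth; used only for
#' depth-ratio copy-number estimation of tandem arrays.
#'
#' @inheritParams simulate_hifi
#' @param read_len read length (default 150).
#' @export
simulate_ilmn <- function(genome, depth, read_len = 150L, seed = 1L) {
  stopifnot(depth > 0)
  with_seed(seed, {
    draw <- function(n) rep(read_len, n)
    sample_reads(genome, depth, draw, "ilmn", 0, "hifi", min_len = 100L)
  })
}
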