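test_that("assembly stats follow the three-N contig rule and NG50", {
  st <- assembly_stats(data.frame(id = "a", bases = "ACGTNNNACGT"), 10)
  expect_equal(st$contig_count, 2L)
  expect_equal(st$total_nonN_bases, 8L)
  expect_equal(sort(st$contig_lengths), c(4L, 4L))

  st2 <- assembly_stats(data.frame(id = "a", bases = "ACGTNNACGT"), 10)
  expect_equal(st2$contig_count, 1L)

  st3 <- assembly_stats(data.frame(id = c("c1", "c2", "c3"),
                                   bases = c(strrep("A", 5), strrep("C", 3),
                                             strrep("G", 2))), 10)
  expect_equal(st3$ng50, 5L)

  expect_error(assembly_stats(data.frame(id = character(0),
                                         bases = character(0)), 10), "empty")
})

test_that("NG50 agrees with the cumulative-sum brute force", {
  set.seed(301)
  for (i in 1:1000) {
    lens <- sample.int(500, sample(1:20, 1), replace = TRUE)
    gsize <- sample.int(sum(lens) * 2, 1)
    fa <- data.frame(id = sprintf("c%d", seq_along(lens)),
                     bases = strrep("A", lens))
    got <- assembly_stats(fa, gsize)$ng50
    expect_identical(got, oracle_ng50(lens, gsize))
  }
})

test_that("coverage profile and band flagging behave per the rules", {
  # constant depth: sd = 0 convention, whole target in band
  aln <- data.frame(start = rep(0L, 30), end = rep(1000L, 30))
  pr <- coverage_profile(aln, 1000L)
  expect_equal(pr$depth, rep(30L, 1000))
  fc <- flag_coverage(pr)
  expect_equal(fc$fraction_in_band, 1.0000)
  expect_equal(nrow(fc$issues), 0L)

  # a 60x region on a 30x background is flagged above-band
  set.seed(302)
  G <- 100000L; rl <- 1000L
  starts <- sample.int(G + rl, 30 * G / rl) - rl
  aln2 <- data.frame(start = pmax(0L, starts), end = pmin(G, starts + rl))
  dup <- aln2[aln2$start < 51000 & aln2$end > 50000, ]
  dup$start <- pmax(dup$start, 50000L); dup$end <- pmin(dup$end, 51000L)
  pr2 <- coverage_profile(rbind(aln2, dup), G)
  fc2 <- flag_coverage(pr2, 3)
  above <- fc2$issues[fc2$issues$kind == "error", ]
  expect_true(nrow(above) > 0 && any(above$start < 51000 & above$end > 50000))
})

test_that("unique markers are canonical k-mers occurring exactly once", {
  # exact 2-copy repeat: no markers inside the repeat
  set.seed(303)
  rep_seq <- random_dna_str(300)
  u1 <- random_dna_str(300); u2 <- random_dna_str(300); u3 <- random_dna_str(300)
  asm <- paste0(u1, rep_seq, u2, rep_seq, u3)
  mk <- unique_markers(asm, k = 21)
  rep_pos <- c(301:(600 - 21), 901:(1200 - 21)) - 1L
  expect_false(any(mk$markers$pos %in% rep_pos))
  # unique flanks are dense with markers
  expect_gt(sum(mk$markers$pos < 280), 250)

  # brute-force canonical k-mer counting on a small case: a planted
  # duplicate 11-mer is not a marker
  set.seed(307)
  a11 <- random_dna_str(11)
  s <- paste0(a11, random_dna_str(15), a11)
  mk2 <- unique_markers(data.frame(id = "s", bases = s), k = 11)
  kmers <- substring(s, 1:(nchar(s) - 10), 11:nchar(s))
  canon <- pmin(kmers, revcomp(kmers))
  uniq <- names(table(canon))[table(canon) == 1]
  expect_equal(nrow(mk2$markers), sum(canon %in% uniq))
  expect_false(0L %in% mk2$markers$pos) # the duplicated leading 11-mer
})

plant_diffs <- function(s, every = 300L) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  at <- seq(every %/% 2, length(ch), by = every)
  ch[at] <- vapply(ch[at], function(x)
    setdiff(c("A", "C", "G", "T"), x)[1], character(1))
  paste(ch, collapse = "")
}

test_that("marker-assisted assignment picks the marker-supported copy", {
  set.seed(304)
  copy1 <- random_dna_str(2000)
  # second copy with a distinguishing substitution every 300 bp
  copy2 <- plant_diffs(copy1, 300L)
  asm <- data.frame(id = "chr",
                    bases = paste0(random_dna_str(500), copy1,
                                   random_dna_str(500), copy2,
                                   random_dna_str(500)))
  mk <- unique_markers(asm, k = 21)
  # a read from copy 1 that multimaps to both copies
  rd <- substr(asm$bases, 501 + 400, 500 + 1600) # inside copy 1
  cand <- data.frame(read_id = "rd", target = "chr",
                     start = c(900L, 3400L), end = c(2100L, 4600L),
                     primary = c(FALSE, TRUE))
  out <- marker_assign(cand, mk$markers, data.frame(id = "rd", bases = rd))
  expect_true(out$assigned[1])
  expect_false(out$assigned[2])
  expect_false(out$low_confidence[1])

  # zero agreeing markers anywhere: primary retained, low-confidence
  cand2 <- data.frame(read_id = "x", target = "chr",
                      start = c(0L, 100L), end = c(50L, 150L),
                      primary = c(TRUE, FALSE))
  out2 <- marker_assign(cand2, mk$markers,
                        data.frame(id = "x", bases = strrep("AT", 30)))
  expect_true(out2$assigned[1])
  expect_true(out2$low_confidence[1])
})

test_that("error-free reads with markers assign 100% correctly", {
  set.seed(305)
  copy1 <- random_dna_str(1500)
  copy2 <- plant_diffs(copy1, 250L)
  flank <- random_dna_str(300)
  asm <- data.frame(id = "chr", bases = paste0(flank, copy1, flank_mid <- random_dna_str(300),
                                               copy2, random_dna_str(300)))
  mk <- unique_markers(asm, k = 21)
  n_ok <- 0L; n_tot <- 0L
  for (i in 1:20) {
    s <- sample(0:700, 1)
    truth_copy <- sample(1:2, 1)
    off <- if (truth_copy == 1) 300L else 300L + 1500L + 300L
    rd <- substr(asm$bases, off + s + 1, off + s + 800)
    # count distinguishing markers in the read's span
    cand <- data.frame(read_id = "r", target = "chr",
                       start = c(off + s, (if (truth_copy == 1) 2100L else 300L) + s),
                       end = c(off + s + 800L, (if (truth_copy == 1) 2100L else 300L) + s + 800L),
                       primary = c(TRUE, FALSE))
    out <- marker_assign(cand, mk$markers, data.frame(id = "r", bases = rd))
    if (out$n_markers[1] > 0) {
      n_tot <- n_tot + 1L
      if (out$assigned[1]) n_ok <- n_ok + 1L
    }
  }
  expect_gt(n_tot, 12L)
  expect_equal(n_ok, n_tot)
})

test_that("allele ratios flag heterozygous-like windows", {
  pile <- data.frame(pos = c(500L), primary = 34, secondary = 1)
  ar <- allele_ratio(pile, 1000L, window = 1000L, min_depth = 10)
  expect_equal(round(ar$fraction, 3), 0.971)
  expect_equal(nrow(ar$issues), 0L)

  pile2 <- data.frame(pos = 0:49, primary = 10, secondary = 10)
  ar2 <- allele_ratio(pile2, 1000L, window = 1000L, min_depth = 10)
  expect_equal(ar2$fraction[1], 0.5)
  expect_equal(ar2$issues$kind, "het_variant")

  pile3 <- data.frame(pos = 0:99, primary = 30, secondary = 0)
  ar3 <- allele_ratio(pile3, 100L, window = 100L)
  expect_equal(ar3$fraction, 1)
})

test_that("windowed identity: identical, mutated and unrelated sequences", {
  set.seed(306)
  a <- random_dna_str(30000)
  wi <- window_identity(a, a, window = 5000, smooth = 10000)
  expect_true(all(wi$identity == 100))

  b <- graphasm:::mutate_identity(a, 0.99)
  wi2 <- window_identity(a, b, window = 5000, smooth = 10000)
  expect_true(all(abs(wi2$identity - 99) < 0.5))

  c2 <- random_dna_str(30000)
  wi3 <- window_identity(a, c2, window = 5000, smooth = 10000)
  expect_true(all(wi3$identity < 90))
  expect_true(all(wi3$identity >= 0 & wi3$identity <= 100))
})

test_that("issue catalog merges per kind and reports affected fraction", {
  iss <- data.frame(target = "chr",
                    start = c(0L, 50L), end = c(100L, 150L),
                    kind = "low_coverage",
                    evidence = "x", stringsAsFactors = FALSE)
  out <- issue_catalog(iss, 1e6)
  expect_equal(nrow(out$catalog), 1L)
  expect_equal(c(out$catalog$start, out$catalog$end), c(0L, 150L))
  expect_equal(out$affected_bases, 150L)

  empty <- issue_catalog(iss[0, ], 1e6)
  expect_equal(empty$affected_bases, 0L)
  expect_equal(empty$affected_pct, 0)

  iss3 <- data.frame(target = "chr", start = 0L, end = 3000L,
                     kind = "error", evidence = "y")
  expect_equal(issue_catalog(iss3, 1e6)$affected_pct, 0.3)
})
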