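test_that("sparse de Bruijn graph: dense limit, doubling, tandem cycles", {
  set.seed(201)
  r <- random_dna_str(120)
  dbg <- build_sparse_dbg(r, k = 15, sample_stride = 1, min_count = 1)
  # dense limit: every k-mer a node, consecutive k-mers the edges
  expect_equal(nrow(dbg$nodes), 120 - 15 + 1)
  expect_true(all(dbg$nodes$count == 1L))

  dbg2 <- build_sparse_dbg(c(r, r), k = 15, sample_stride = 1, min_count = 1)
  expect_equal(nrow(dbg2$nodes), nrow(dbg$nodes))
  expect_true(all(dbg2$nodes$count == 2L))
  expect_true(all(dbg2$edges$n == 2L * dbg$edges$n[
    match(paste(dbg2$edges$from, dbg2$edges$to),
          paste(dbg$edges$from, dbg$edges$to))]))

  # tandem 3-copy unit read collapses into a cycle: far fewer nodes than
  # k-mer positions
  unit <- random_dna_str(60)
  tandem <- strrep(unit, 3)
  dbg3 <- build_sparse_dbg(tandem, k = 15, sample_stride = 1, min_count = 1)
  expect_equal(nrow(dbg3$nodes), 60L) # one k-mer per unit phase: a cycle
  expect_true(any(dbg3$edges$n >= 2))

  expect_warning(build_sparse_dbg(c("ACGT", r), k = 15, sample_stride = 1),
                 "shorter than k")
})

test_that("walk extraction denoises reads toward the truth", {
  set.seed(202)
  genome <- data.frame(id = "arr", bases = random_dna_str(6000))
  reads <- simulate_ont(genome, depth = 30, mean_len = 3000,
                        error_rate = 0.05, seed = 203)
  dbg <- build_sparse_dbg(reads, k = 15, sample_stride = 5)
  # error-free reads through an error-free graph: the walk is (a flank-
  # trimmed copy of) the read itself
  clean <- data.frame(id = c("c1", "c2", "c3"),
                      bases = substring(genome$bases, c(1, 1001, 2001),
                                        c(2500, 3500, 4500)))
  dbg0 <- build_sparse_dbg(clean, k = 15, sample_stride = 5, min_count = 2)
  w0 <- extract_walks(clean, dbg0, min_anchors = 2)
  expect_true(grepl(w0$bases[2], clean$bases[2], fixed = TRUE))
  expect_gte(nchar(w0$bases[2]), nchar(clean$bases[2]) - 30L)

  # noisy reads: walk closer to truth than the read is
  better <- 0L
  for (i in 1:10) {
    tr <- substr(genome$bases, reads$truth_start[i] + 1, reads$truth_end[i])
    w <- extract_walks(reads[i, ], dbg)
    if (nrow(w) == 0) next
    wb <- if (reads$truth_strand[i] == "-") revcomp(w$bases[1]) else w$bases[1]
    rb <- if (reads$truth_strand[i] == "-") revcomp(reads$bases[i]) else reads$bases[i]
    d_walk <- graphasm:::cpp_banded_edit(wb, tr, 300L)
    d_read <- graphasm:::cpp_banded_edit(rb, tr, 300L)
    if (d_walk < d_read) better <- better + 1L
  }
  expect_gte(better, 8L)

  # a read from unrelated sequence is omitted
  set.seed(204)
  alien <- data.frame(id = "alien", bases = random_dna_str(2000))
  wa <- extract_walks(alien, dbg)
  expect_equal(nrow(wa), 0L)
  expect_equal(attr(wa, "n_omitted"), 1L)
})

test_that("unit segmentation tiles arrays and tolerates indels", {
  set.seed(205)
  unit <- random_dna_str(100)
  arr <- strrep(unit, 10)
  u <- segment_units(arr, unit)
  expect_equal(sum(u$complete), 10L)
  expect_true(all(u$end - u$start == 100L))

  # extra flanks become incomplete pieces
  arr2 <- paste0(random_dna_str(30), arr, random_dna_str(30))
  u2 <- segment_units(arr2, unit)
  expect_equal(sum(u2$complete), 10L)
  expect_equal(sum(!u2$complete), 2L)

  # a 6 bp insertion in one copy: still 10 units, that one longer
  ins_at <- 950L
  arr3 <- paste0(substr(arr, 1, ins_at), "ACGTCA",
                 substr(arr, ins_at + 1, nchar(arr)))
  u3 <- segment_units(arr3, unit)
  expect_equal(sum(u3$complete), 10L)
  expect_true(any(u3$end[u3$complete] - u3$start[u3$complete] == 106L))

  expect_equal(nrow(segment_units(random_dna_str(500), unit)), 0L)
})

test_that("morph clustering separates at the identity threshold", {
  set.seed(206)
  A <- random_dna_str(800)
  # exactly 8 substitutions (99.0% identity), deterministic
  B <- local({
    ch <- strsplit(A, "", fixed = TRUE)[[1]]
    at <- seq(50, 750, length.out = 8)
    ch[at] <- vapply(ch[at], function(x)
      setdiff(c("A", "C", "G", "T"), x)[1], character(1))
    paste(ch, collapse = "")
  })
  units <- data.frame(source = sprintf("r%d", 1:12), ordinal = 1:12,
                      start = 0L, end = 800L,
                      bases = c(rep(A, 8), rep(B, 4)),
                      complete = TRUE, stringsAsFactors = FALSE)
  cm <- cluster_morphs(units, 0.995)
  expect_equal(nrow(cm$morphs), 2L)
  expect_equal(sort(cm$morphs$n_units), c(4L, 8L))
  expect_setequal(cm$morphs$bases, c(A, B))

  # twelve identical units -> a single morph
  units1 <- units; units1$bases <- A
  cm1 <- cluster_morphs(units1, 0.995)
  expect_equal(nrow(cm1$morphs), 1L)

  # clustering is invariant to input order
  perm <- sample(12)
  cmp <- cluster_morphs(units[perm, ], 0.995)
  expect_equal(sort(cmp$morphs$n_units), sort(cm$morphs$n_units))
  expect_setequal(cmp$morphs$bases, cm$morphs$bases)
})

test_that("unit polishing removes noise but preserves morph variants", {
  set.seed(207)
  A <- random_dna_str(600)
  B <- graphasm:::mutate_identity(A, 0.99)
  noisy <- c(vapply(rep(A, 16), graphasm:::apply_errors, character(1),
                    error_rate = 0.03, mode = "ont"),
             vapply(rep(B, 8), graphasm:::apply_errors, character(1),
                    error_rate = 0.03, mode = "ont"))
  units <- data.frame(source = sprintf("r%d", seq_along(noisy)),
                      ordinal = 1L, start = 0L, end = nchar(noisy),
                      bases = noisy, complete = TRUE,
                      stringsAsFactors = FALSE)
  pol <- polish_units(units, A)
  idA <- vapply(pol$bases, seq_identity, numeric(1), b = A, band = 60)
  idB <- vapply(pol$bases, seq_identity, numeric(1), b = B, band = 60)
  expect_true(all(pmax(idA, idB) > 99.5))
  expect_equal(sum(idA > idB), 16L)
  expect_equal(sum(idB > idA), 8L)
})

test_that("copy numbers follow the read-support rule", {
  m <- data.frame(id = c("morph1", "morph2"), bases = "A",
                  n_units = c(40L, 4L), stringsAsFactors = FALSE)
  out <- estimate_copy_number(m, 10)
  expect_equal(out$copy_number, c(4L, 1L))
  expect_error(estimate_copy_number(m, 0), "depth")
  # rounding is to nearest with ties up
  m2 <- data.frame(id = "m", bases = "A", n_units = 25L)
  expect_equal(estimate_copy_number(m2, 10)$copy_number, 3L)
})

test_that("array copy estimate is the depth ratio", {
  expect_equal(estimate_array_copies_by_depth(100, 10), 10)
  expect_equal(estimate_array_copies_by_depth(30, 30), 1)
  expect_error(estimate_array_copies_by_depth(10, 0), "base_depth")

  # simulated 20-copy toy array, 50x short reads: within +-2
  set.seed(208)
  unit <- random_dna_str(300)
  sp <- genome_spec(seed = 209, backbone_len = 30000L,
                    satellites = list(list(unit = unit, copies = 20L,
                                           divergence = 0, pos = 10000L)))
  sim <- simulate_genome(sp)
  reads <- simulate_ilmn(sim$genome, depth = 50, seed = 210)
  arr <- sim$truth$placements[sim$truth$placements$kind == "satellite", ]
  ov <- pmax(0, pmin(reads$truth_end, arr$end) -
               pmax(reads$truth_start, arr$start))
  # depth over the collapsed (single-unit) representation vs genome depth
  unit_depth <- sum(ov) / 300
  base_depth <- (sum(reads$truth_end - reads$truth_start) - sum(ov)) /
    (30000 - (arr$end - arr$start))
  est <- estimate_array_copies_by_depth(unit_depth, base_depth)
  expect_lt(abs(est - 20), 2)
})

test_that("morph graph layout: unique orders vs model fallbacks", {
  # single morph head-to-tail -> unique walk, model = FALSE
  units1 <- data.frame(source = "r1", ordinal = 1:5, start = 0L, end = 1L,
                       bases = "A", complete = TRUE, stringsAsFactors = FALSE)
  mg1 <- build_morph_graph(units1, rep("morphA", 5))
  lay1 <- layout_array(mg1, c(morphA = 5L))
  expect_false(lay1$model)
  expect_equal(lay1$order, rep("morphA", 5))

  # fully spanned alternation A,B,A,B -> that order, model = FALSE
  units2 <- data.frame(source = "r1", ordinal = 1:4, start = 0L, end = 1L,
                       bases = "A", complete = TRUE, stringsAsFactors = FALSE)
  mg2 <- build_morph_graph(units2, c("A", "B", "A", "B"))
  lay2 <- layout_array(mg2, c(A = 2L, B = 2L))
  expect_false(lay2$model)
  expect_equal(lay2$order, c("A", "B", "A", "B"))

  # reads too short to order two interleaved morphs -> blocks, model = TRUE
  units3 <- do.call(rbind, lapply(1:6, function(r)
    data.frame(source = sprintf("s%d", r), ordinal = 1:2, start = 0L,
               end = 1L, bases = "A", complete = TRUE,
               stringsAsFactors = FALSE)))
  asg3 <- c("A", "B", "B", "A", "A", "B", "B", "A", "A", "B", "A", "A")
  mg3 <- build_morph_graph(units3, asg3)
  lay3 <- layout_array(mg3, c(A = 8L, B = 4L))
  expect_true(lay3$model)
  expect_equal(lay3$order, c(rep("A", 8), rep("B", 4)))

  # no spanning reads at all -> blocks, model = TRUE
  mg0 <- build_morph_graph(units1[1, , drop = FALSE], "A")
  expect_true(layout_array(mg0, c(A = 8L, B = 4L))$model)
})

test_that("emitted units are head-to-tail; total length tracks the array", {
  sp <- genome_spec(seed = 211, backbone_len = 14000L,
                    rdna = list(unit_len = 800L, morphs = 2L, identity = 0.99,
                                copy_numbers = c(8L, 4L),
                                arrangement = "shuffled", pos = 2000L))
  sim <- simulate_genome(sp)
  ont <- simulate_ont(sim$genome, depth = 40, mean_len = 15000, seed = 212)
  ref_unit <- sim$truth$morphs$bases[1]
  res <- analyze_rdna_array(ont, ref_unit, 0.995)
  # all emitted units align forward (head-to-tail) to the reference
  comp <- res$units[res$units$complete, ]
  fwd <- vapply(comp$bases[1:20], function(u) {
    d_f <- graphasm:::cpp_banded_edit(u, ref_unit, 120L)
    d_r <- graphasm:::cpp_banded_edit(revcomp(u), ref_unit, 120L)
    d_f < d_r
  }, logical(1))
  expect_true(all(fwd))
  # sum of copy numbers x unit length within 10% of the true array length
  est_len <- sum(res$morphs$copy_number) * 800
  expect_lt(abs(est_len - 9600) / 9600, 0.1)
})
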