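test_that("error-free reads tiling a unique genome collapse to one node", {
  sp <- genome_spec(seed = 71, backbone_len = 2000L)
  g <- simulate_genome(sp)
  starts <- seq(0L, 1440L, by = 360L)
  reads <- data.frame(id = sprintf("r%d", seq_along(starts)),
                      bases = substring(g$genome$bases, starts + 1,
                                        pmin(2000L, starts + 560L)),
                      stringsAsFactors = FALSE)
  hpc <- hpc_compress_set(reads)
  ov <- exact_overlaps(hpc, min_overlap = 100, k = 15, w = 1)
  gr <- build_graph(hpc, ov)
  expect_equal(nrow(gr$nodes), 1L)
  expect_equal(nrow(gr$edges), 0L)
  expect_equal(gr$nodes$support, 5L)
  # the unitig spells the genome (up to strand) in compressed space
  expect_equal(seq_identity(gr$nodes$bases,
                            hpc_compress(g$genome$bases)$bases, band = 32),
               100)
})

test_that("a repeat longer than every read becomes a high-degree node", {
  # genome U1.R.U2.R.U3 with R longer than the reads
  set.seed(72)
  U <- vapply(rep(1500L, 3), random_dna_str, character(1))
  R <- random_dna_str(1200L)
  genome <- data.frame(id = "chr", bases = paste0(U[1], R, U[2], R, U[3]))
  reads <- simulate_hifi(genome, depth = 20, mean_len = 700, error_rate = 0,
                         seed = 73)
  hpc <- hpc_compress_set(reads)
  ov <- exact_overlaps(hpc, min_overlap = 150, k = 15, w = 2)
  gr <- build_graph(hpc, ov)
  gr <- simplify_graph(gr, tip_len = 2000, bubble_len = 200)
  expect_gte(nrow(gr$nodes), 5L)
  # one node (the repeat core) carries four incident edge-ends
  idx <- setNames(seq_len(nrow(gr$nodes)), gr$nodes$id)
  degree <- integer(nrow(gr$nodes))
  for (r in seq_len(nrow(gr$edges))) {
    degree[idx[gr$edges$from[r]]] <- degree[idx[gr$edges$from[r]]] + 1L
    degree[idx[gr$edges$to[r]]] <- degree[idx[gr$edges$to[r]]] + 1L
  }
  expect_true(any(degree >= 4L))
})

test_that("empty overlap list yields singleton nodes; unknown read errors", {
  hpc <- hpc_compress_set(data.frame(id = c("a", "b", "c"),
                                     bases = c("ACGTACA", "GGTACCA",
                                               "TTGACAG")))
  empty <- exact_overlaps(hpc, min_overlap = 7, k = 4, w = 1)
  gr <- build_graph(hpc, empty)
  expect_equal(nrow(gr$nodes), 3L)
  bad <- data.frame(from = "zz", to = "a", from_idx = 9L, to_idx = 1L,
                    from_orient = "+", to_orient = "+", len = 5L,
                    exact = TRUE, contained = NA_character_,
                    from_start = 0L, from_end = 5L, to_start = 0L,
                    to_end = 5L, strand = "+", diag = 0L, a_idx = 9L,
                    b_idx = 1L)
  expect_error(build_graph(hpc, bad), "unknown read")
})

test_that("simplification removes transitive edges, tips, and bubbles", {
  # transitive triangle a->b, b->c, a->c: ext additivity holds by length
  g <- make_graph(c("a", "b", "c"), c(1000L, 1000L, 1000L),
                  data.frame(from = c("a", "b", "a"),
                             from_orient = "+",
                             to = c("b", "c", "c"),
                             to_orient = "+",
                             len = c(600L, 600L, 200L),
                             stringsAsFactors = FALSE))
  ve <- graphasm:::graph_vertex_edges(g)
  red <- graphasm:::reduce_transitive(ve, g$nodes$len, fuzz = 10L)
  # the direct a->c edge is removed, its complement too
  expect_equal(nrow(red), 4L)
  idx <- c(a = 1L, b = 2L, c = 3L)
  expect_false(any(graphasm:::vread(red$u) == 1L &
                     graphasm:::vread(red$w) == 3L))

  # 200 bp dead-end spur at 1x depth off a 30x backbone: clipped (and the
  # backbone then merges into a single node)
  g2 <- make_graph(c("bb1", "bb2", "spur"), c(5000L, 5000L, 200L),
                   data.frame(from = c("bb1", "bb1"), from_orient = "+",
                              to = c("bb2", "spur"), to_orient = "+",
                              len = c(500L, 100L), stringsAsFactors = FALSE),
                   depth = c(30, 30, 1))
  s2 <- simplify_graph(g2, tip_len = 1000L, bubble_len = 500L)
  expect_equal(nrow(s2$nodes), 1L)

  # two parallel 1 kbp paths at 15x between shared ends, bubble_len 500:
  # untouched
  g3 <- make_graph(c("L", "p1", "p2", "Rn"), c(3000L, 1000L, 1000L, 3000L),
                   data.frame(from = c("L", "L", "p1", "p2"),
                              from_orient = "+",
                              to = c("p1", "p2", "Rn", "Rn"),
                              to_orient = "+",
                              len = c(100L, 100L, 100L, 100L),
                              stringsAsFactors = FALSE),
                   depth = c(30, 15, 15, 30))
  s3 <- simplify_graph(g3, tip_len = 500L, bubble_len = 500L)
  expect_equal(nrow(s3$nodes), 4L)
  # ... but with bubble_len 1200 the lower-depth branch pops
  g4 <- g3
  g4$nodes$depth <- c(30, 18, 12, 30)
  s4 <- simplify_graph(g4, tip_len = 500L, bubble_len = 1200L)
  expect_equal(nrow(s4$nodes), 1L) # popped branch merged away
})

test_that("multiplicity estimation follows the depth-ratio rule", {
  g <- make_graph(c("x", "y", "z"), c(8000L, 8000L, 8000L),
                  data.frame(from = character(0), from_orient = character(0),
                             to = character(0), to_orient = character(0),
                             len = integer(0)),
                  depth = c(70, 33, 3))
  g <- estimate_multiplicity(g, base_depth = 35, noise_frac = 0.2)
  expect_equal(g$nodes$multiplicity, c(2L, 1L, 0L))
  expect_error(estimate_multiplicity(g, base_depth = 0), "base_depth")
})

test_that("flow refinement raises the multiplicity of shared repeat cores", {
  g <- make_graph(c("R", "A", "B", "C", "D"),
                  c(2000L, 5000L, 5000L, 5000L, 5000L),
                  data.frame(from = c("A", "C", "R", "R"), from_orient = "+",
                             to = c("R", "R", "B", "D"), to_orient = "+",
                             len = 100L, stringsAsFactors = FALSE),
                  depth = c(10, 25, 25, 25, 25))
  g <- estimate_multiplicity(g)
  expect_equal(g$nodes$multiplicity[g$nodes$id == "R"], 2L)
  expect_true(all(g$nodes$multiplicity[g$nodes$id != "R"] == 1L))
})

test_that("GFA round trip preserves topology, sequences and tags", {
  path <- withr::local_tempfile(fileext = ".gfa")
  g <- make_graph(c("n1", "n2"), c(500L, 400L),
                  data.frame(from = "n1", from_orient = "+", to = "n2",
                             to_orient = "-", len = 120L,
                             stringsAsFactors = FALSE),
                  depth = c(12.5, 30), mult = c(1L, 2L))
  export_gfa(g, path)
  back <- import_gfa(path)
  expect_equal(back$nodes$id, g$nodes$id)
  expect_equal(back$nodes$bases, g$nodes$bases)
  expect_equal(back$nodes$depth, g$nodes$depth, tolerance = 1e-4)
  expect_equal(back$nodes$multiplicity, g$nodes$multiplicity)
  expect_equal(back$edges, g$edges, ignore_attr = TRUE)

  # empty graph -> header-only file
  g0 <- make_graph(character(0), integer(0),
                   data.frame(from = character(0), from_orient = character(0),
                              to = character(0), to_orient = character(0),
                              len = integer(0)))
  g0$nodes <- g0$nodes[0, ]
  export_gfa(g0, path)
  expect_equal(readLines(path), "H\tVN:Z:1.0")
  expect_equal(nrow(import_gfa(path)$nodes), 0L)

  # random 50-node graph: edge multiset preserved
  set.seed(99)
  ids <- sprintf("v%02d", 1:50)
  ed <- data.frame(from = sample(ids, 60, TRUE), from_orient = sample(c("+", "-"), 60, TRUE),
                   to = sample(ids, 60, TRUE), to_orient = sample(c("+", "-"), 60, TRUE),
                   len = sample(50:500, 60, TRUE), stringsAsFactors = FALSE)
  ed <- ed[!duplicated(ed[, 1:4]), ]
  gg <- make_graph(ids, rep(600L, 50), ed)
  export_gfa(gg, path)
  b2 <- import_gfa(path)
  key <- function(e) sort(paste(e$from, e$from_orient, e$to, e$to_orient, e$len))
  expect_equal(key(b2$edges), key(gg$edges))

  writeLines(c("H\tVN:Z:1.0", "S\tonly_id"), path)
  expect_error(import_gfa(path), "malformed")
})
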