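test_that("candidate enumeration handles chains, X-tangles and loops", {
  # linear chain a-b-c, all multiplicity 1 -> exactly one candidate
  chain <- make_graph(c("a", "b", "c"), c(500L, 500L, 500L),
                      data.frame(from = c("a", "b"), from_orient = "+",
                                 to = c("b", "c"), to_orient = "+",
                                 len = 100L, stringsAsFactors = FALSE),
                      mult = c(1L, 1L, 1L))
  cands <- enumerate_candidates(chain)
  expect_length(cands, 1L)
  expect_length(cands[[1]], 1L)
  expect_equal(cands[[1]][[1]]$steps$node, c("a", "b", "c"))
  expect_equal(cands[[1]][[1]]$status, "resolved")

  # X-tangle: A,C -> R(x2) -> B,D gives exactly the two pairings
  x <- make_graph(c("R", "A", "B", "C", "D"), c(800L, rep(2000L, 4)),
                  data.frame(from = c("A", "C", "R", "R"), from_orient = "+",
                             to = c("R", "R", "B", "D"), to_orient = "+",
                             len = 100L, stringsAsFactors = FALSE),
                  mult = c(2L, 1L, 1L, 1L, 1L))
  cx <- enumerate_candidates(x)
  expect_length(cx, 2L)
  sig <- vapply(cx, function(cand)
    paste(sort(vapply(cand, function(w) {
      fwd <- paste(w$steps$node, collapse = "")
      rev <- paste(rev(w$steps$node), collapse = "")
      min(fwd, rev)
    }, character(1))), collapse = "|"), character(1))
  expect_setequal(sig, c("ARB|CRD", "ARD|BRC"))

  # loop node with multiplicity 2 on a backbone: traversed exactly twice
  loop <- make_graph(c("L", "M", "Rt"), c(2000L, 600L, 2000L),
                     data.frame(from = c("L", "M", "M"), from_orient = "+",
                                to = c("M", "M", "Rt"), to_orient = "+",
                                len = 100L, stringsAsFactors = FALSE),
                     mult = c(1L, 2L, 1L))
  cl <- enumerate_candidates(loop)
  expect_length(cl, 1L)
  expect_equal(cl[[1]][[1]]$steps$node, c("L", "M", "M", "Rt"))
})

test_that("candidate enumeration agrees with the Eulerian brute force", {
  set.seed(101)
  trials <- 0L
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    ids <- letters[seq_len(n)]
    # generate a random true walk visiting nodes with repeats, forward
    # orientation only, then build the graph it implies
    walk <- sample(c(ids, sample(ids, sample(0:3, 1), replace = TRUE)))
    mult <- table(factor(walk, levels = ids))
    edges <- unique(data.frame(from = walk[-length(walk)], from_orient = "+",
                               to = walk[-1], to_orient = "+",
                               len = 50L, stringsAsFactors = FALSE))
    g <- make_graph(ids, rep(300L, n), edges, mult = as.integer(mult))
    cands <- enumerate_candidates(g, max_candidates = 3000L)
    got <- sort(vapply(cands, cand_signature, character(1), ids = ids))
    vedges <- data.frame(u = ifelse(edges$from_orient == "+",
                                    2L * match(edges$from, ids) - 1L,
                                    2L * match(edges$from, ids)),
                         w = 2L * match(edges$to, ids) - 1L)
    vedges <- rbind(vedges,
                    data.frame(u = ifelse(vedges$w %% 2L == 1L, vedges$w + 1L,
                                          vedges$w - 1L),
                               w = ifelse(vedges$u %% 2L == 1L, vedges$u + 1L,
                                          vedges$u - 1L)))
    vedges <- unique(vedges)
    want <- oracle_candidates(n, vedges, as.integer(mult))
    expect_equal(got, want)
    trials <- trials + 1L
  }
  expect_gte(trials, 15L)
})

test_that("ultra-long reads align to node paths through the graph", {
  set.seed(103)
  A <- random_dna_str(2500); R <- random_dna_str(1200); B <- random_dna_str(2500)
  g <- make_graph(c("A", "R", "B"), c(2500L, 1200L, 2500L),
                  data.frame(from = c("A", "R"), from_orient = "+",
                             to = c("R", "B"), to_orient = "+", len = 0L,
                             stringsAsFactors = FALSE),
                  mult = c(1L, 2L, 1L), bases = c(A, R, B))
  # error-free read across A-suffix . R . B-prefix
  rd <- paste0(substr(A, 1501, 2500), R, substr(B, 1, 1000))
  al <- align_ont_to_graph(data.frame(id = "read1", bases = rd), g,
                           compress = FALSE)
  expect_length(al, 1L)
  expect_equal(al[[1]]$path$node, c("A", "R", "B"))
  expect_equal(al[[1]]$path$orient, c("+", "+", "+"))

  # read entirely inside one long node -> single-node path
  al2 <- align_ont_to_graph(data.frame(id = "r2",
                                       bases = substr(A, 301, 1900)), g,
                            compress = FALSE)
  expect_equal(al2[[1]]$path$node, "A")

  # 5%-error reads over the known path recover it in >= 95% of trials
  ok <- 0L
  for (t in 1:100) {
    noisy <- graphasm:::apply_errors(rd, 0.05, "ont")
    a <- align_ont_to_graph(data.frame(id = "n", bases = noisy), g,
                            compress = FALSE)
    if (length(a) == 1 && identical(a[[1]]$path$node, c("A", "R", "B")))
      ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("walk selection follows support and margin rules", {
  x <- make_graph(c("R", "A", "B", "C", "D"), c(800L, rep(2000L, 4)),
                  data.frame(from = c("A", "C", "R", "R"), from_orient = "+",
                             to = c("R", "R", "B", "D"), to_orient = "+",
                             len = 100L, stringsAsFactors = FALSE),
                  mult = c(2L, 1L, 1L, 1L, 1L))
  cands <- enumerate_candidates(x)
  path_of <- function(nodes) list(read_id = "x",
                                  path = data.frame(node = nodes,
                                                    orient = "+"),
                                  n_anchors = 10L, span = 1000L)
  support_ARB <- replicate(6, path_of(c("A", "R", "B")), simplify = FALSE)
  sel <- select_walk(cands, support_ARB, x, min_margin = 2)
  expect_equal(attr(sel, "status"), "resolved")
  sigs <- vapply(sel, function(w) paste(w$steps$node, collapse = ""),
                 character(1))
  expect_true(any(grepl("ARB", sigs)) || any(grepl("BRA", sigs)))

  # 3 vs 3 support with margin 2 -> ambiguous
  mixed <- c(replicate(3, path_of(c("A", "R", "B")), simplify = FALSE),
             replicate(3, path_of(c("A", "R", "D")), simplify = FALSE))
  sel2 <- select_walk(cands, mixed, x, min_margin = 2)
  expect_equal(attr(sel2, "status"), "ambiguous")

  # single candidate resolves without evidence
  chain <- make_graph(c("a", "b"), c(500L, 500L),
                      data.frame(from = "a", from_orient = "+", to = "b",
                                 to_orient = "+", len = 100L,
                                 stringsAsFactors = FALSE),
                      mult = c(1L, 1L))
  sel3 <- select_walk(enumerate_candidates(chain), list(), chain)
  expect_equal(attr(sel3, "status"), "resolved")
})

test_that("run-length consensus takes the modal run, smaller on ties", {
  bases <- "ACGT"
  mkread <- function(id, runs) list(id = id, runs = as.integer(runs))
  reads <- list(mkread("r1", c(3, 2, 1, 1)), mkread("r2", c(3, 2, 1, 1)),
                mkread("r3", c(3, 3, 1, 1)), mkread("r4", c(2, 3, 1, 1)))
  hpc <- structure(list(id = vapply(reads, `[[`, "", "id"),
                        bases = rep(bases, 4),
                        runs = lapply(reads, `[[`, "runs"),
                        meta = data.frame(id = vapply(reads, `[[`, "", "id"))),
                   class = "hpc_set")
  g <- make_graph("n1", 4L, data.frame(from = character(0),
                                       from_orient = character(0),
                                       to = character(0),
                                       to_orient = character(0),
                                       len = integer(0)), bases = bases)
  g$placements <- data.frame(node = "n1", read_id = hpc$id, offset = 0L,
                             orient = "+", read_len = 4L)
  walk <- list(id = "w1", steps = data.frame(node = "n1", orient = "+"),
               status = "resolved")
  cons <- walk_consensus(walk, g, hpc)
  # position 1: runs {3,3,3,2} -> 3; position 2: {2,2,3,3} -> tie -> 2
  expect_identical(cons$bases, paste0(strrep("A", 3), strrep("C", 2), "G", "T"))
})

test_that("error-free end-to-end assembly reproduces the genome exactly", {
  sp <- genome_spec(seed = 81, backbone_len = 20000L)
  sim <- simulate_genome(sp)
  reads <- simulate_hifi(sim$genome, depth = 15, mean_len = 3000,
                         error_rate = 0, seed = 82)
  res <- assemble(reads, min_overlap = 300L)
  expect_equal(nrow(res$assembly), 1L)
  expect_equal(res$assembly$status, "resolved")
  cons <- res$assembly$bases
  expect_true(cons == sim$genome$bases || cons == revcomp(sim$genome$bases))
})
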