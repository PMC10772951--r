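make_cluster <- function(seed, members, score) {
  structure(list(seed = seed, members = sort(members), score = score),
            class = "kmer_cluster")
}

make_digraph <- function(vertices_df, members, edges_df, k) {
  structure(list(vertices = vertices_df, members = members,
                 edges = edges_df, k = k),
            class = "cluster_digraph")
}

occ_df <- function(seqname, start, L = 6, strand = "+") {
  data.frame(seqname = seqname, start = start, end = start + L,
             strand = strand, word = strrep("A", L), stringsAsFactors = FALSE)
}

test_that("cluster digraph aggregates member-level DBG weights", {
  seqs <- Biostrings::DNAStringSet("TTAGCTAGCTT")
  dbg <- build_debruijn_graph(seqs, c("AGCTAG", "GCTAGC"), 6)
  clusters <- list(make_cluster("AGCTAG", "AGCTAG", 2),
                   make_cluster("GCTAGC", "GCTAGC", 1))
  gc_graph <- build_cluster_digraph(dbg, clusters)
  expect_equal(gc_graph$vertices$id, c("C001", "C002"))
  e <- gc_graph$edges[gc_graph$edges$from == "C001" &
                        gc_graph$edges$to == "C002", ]
  expect_equal(e$w, dbg$edges$w[dbg$edges$u == "AGCTAG"])
})

test_that("parallel member edges sum into one cluster edge", {
  # two clusters of two members each; both member-level edges present
  seqs <- Biostrings::DNAStringSet(c("AAAAACA", "AAAAACA", "CAAAACG"))
  k <- 5
  vertices <- unique(iter_kmers(seqs, k, both_strands = TRUE)$kmer)
  dbg <- build_debruijn_graph(seqs, vertices, k)
  clusters <- list(make_cluster("AAAAA", c("AAAAA", "CAAAA"), 2),
                   make_cluster("AAAAC", c("AAAAC", "AAACG"), 1))
  gc_graph <- build_cluster_digraph(dbg, clusters)
  e <- gc_graph$edges[gc_graph$edges$from == "C001" &
                        gc_graph$edges$to == "C002", ]
  # brute-force member-pair sum over the DBG
  expected <- 0
  for (u in clusters[[1]]$members) for (v in clusters[[2]]$members) {
    hit <- dbg$edges$w[dbg$edges$u == u & dbg$edges$v == v]
    if (length(hit) == 1) expected <- expected + hit
  }
  expect_gt(expected, 0)
  expect_equal(e$w, expected)
})

test_that("cluster digraph weights match the member-pair oracle on random input", {
  set.seed(5)
  strs <- replicate(8, random_dna(60))
  seqs <- Biostrings::DNAStringSet(strs)
  k <- 5
  vertices <- unique(iter_kmers(seqs, k, both_strands = TRUE)$kmer)
  dbg <- build_debruijn_graph(seqs, vertices, k)
  # draw cluster members from DBG edge endpoints so cross-cluster edges exist
  picked <- dbg$edges[sample(nrow(dbg$edges), 12), ]
  us <- unique(picked$u)
  vs <- setdiff(unique(picked$v), us)
  rest <- setdiff(vertices, c(us, vs))
  clusters <- list(
    make_cluster(us[1], us, 3),
    make_cluster(vs[1], vs, 2),
    make_cluster(rest[1], rest[1:4], 1)
  )
  gc_graph <- build_cluster_digraph(dbg, clusters)
  expect_gt(nrow(gc_graph$edges), 0)
  for (i in seq_len(nrow(gc_graph$edges))) {
    from <- gc_graph$edges$from[i]
    to <- gc_graph$edges$to[i]
    expected <- 0
    for (u in gc_graph$members[[from]]) for (v in gc_graph$members[[to]]) {
      hit <- dbg$edges$w[dbg$edges$u == u & dbg$edges$v == v]
      if (length(hit) == 1) expected <- expected + hit
    }
    expect_equal(gc_graph$edges$w[i], expected)
  }
})

test_that("multi-cluster k-mers go to the higher-f cluster before aggregation", {
  seqs <- Biostrings::DNAStringSet("TTAGCTAGCTT")
  dbg <- build_debruijn_graph(seqs, c("AGCTAG", "GCTAGC"), 6)
  clusters <- list(make_cluster("AGCTAG", c("AGCTAG", "GCTAGC"), 5),
                   make_cluster("GCTAGC", "GCTAGC", 1))
  gc_graph <- build_cluster_digraph(dbg, clusters)
  expect_equal(gc_graph$members[["C001"]], c("AGCTAG", "GCTAGC"))
  expect_equal(gc_graph$members[["C002"]], character(0))
  # the member-level edge is now internal: recorded as a self-loop
  expect_true(all(gc_graph$edges$from == "C001" & gc_graph$edges$to == "C001"))
})

test_that("path extension follows the greedy heaviest-edge trace", {
  # chain U3 -> U2 -> U1 -> S -> D1 -> D2 -> D3 with weights decreasing
  # away from the start; k = 6 so the 6-edge budget (<= 12) never binds
  ids <- c("U3", "U2", "U1", "S", "D1", "D2", "D3")
  v <- data.frame(id = ids, seed = ids,
                  f = c(1, 2, 3, 10, 3, 2, 1) / 10,
                  n_members = 1, stringsAsFactors = FALSE)
  v <- v[order(-v$f, v$seed), ]
  edges <- data.frame(
    from = c("U3", "U2", "U1", "S", "D1", "D2"),
    to = c("U2", "U1", "S", "D1", "D2", "D3"),
    w = c(1, 2, 3, 4, 2.5, 1.5), stringsAsFactors = FALSE)
  gc_graph <- make_digraph(v, stats::setNames(as.list(ids), ids), edges, 6)
  paths <- extend_paths(gc_graph, 6)
  expect_length(paths, 1)
  expect_equal(paths[[1]]$vertices, ids)
  expect_equal(paths[[1]]$start, "S")
  expect_equal(paths[[1]]$upstream, c("U3", "U2", "U1", "S"))
  expect_equal(paths[[1]]$downstream, c("S", "D1", "D2", "D3"))
})

test_that("per-direction cap, length cap and coverage hold", {
  # long chain: at most 3 vertices may be added downstream
  ids <- sprintf("N%d", 1:8)
  v <- data.frame(id = ids, seed = ids, f = rev(seq_along(ids)) / 10,
                  n_members = 1, stringsAsFactors = FALSE)
  edges <- data.frame(from = ids[-8], to = ids[-1], w = 8:2,
                      stringsAsFactors = FALSE)
  gc_graph <- make_digraph(v, stats::setNames(as.list(ids), ids), edges, 6)
  paths <- extend_paths(gc_graph, 6)
  expect_equal(paths[[1]]$vertices, ids[1:4])  # start N1 + 3 downstream
  # every vertex covered across emitted paths
  expect_setequal(unique(unlist(lapply(paths, `[[`, "vertices"))), ids)
  # length cap: with k = 16 only 18 - 16 = 2 edges are allowed
  paths16 <- extend_paths(gc_graph, 16)
  expect_equal(length(paths16[[1]]$vertices), 3L)

  # isolated vertex yields a single-vertex path
  v1 <- data.frame(id = "X", seed = "X", f = 1, n_members = 1,
                   stringsAsFactors = FALSE)
  p1 <- extend_paths(make_digraph(v1, list(X = "X"),
                                  data.frame(from = character(),
                                             to = character(),
                                             w = numeric()), 6), 6)
  expect_equal(p1[[1]]$vertices, "X")
})

test_that("self-loops are never traversed during extension", {
  v <- data.frame(id = c("A", "B"), seed = c("A", "B"), f = c(2, 1) / 10,
                  n_members = 1, stringsAsFactors = FALSE)
  edges <- data.frame(from = c("A", "A"), to = c("A", "B"), w = c(100, 1),
                      stringsAsFactors = FALSE)
  gc_graph <- make_digraph(v, list(A = "A", B = "B"), edges, 6)
  paths <- extend_paths(gc_graph, 6)
  expect_equal(paths[[1]]$vertices, c("A", "B"))
})

test_that("collect_occurrences finds direct and spelled-pair matches", {
  seqs <- Biostrings::DNAStringSet(c(s1 = "TTTACGTACTT"))
  gc_graph <- make_digraph(
    data.frame(id = "C001", seed = "ACGTAC", f = 1, n_members = 1),
    list(C001 = "ACGTAC"),
    data.frame(from = character(), to = character(), w = numeric()), 6)
  occ <- collect_occurrences("C001", gc_graph, seqs, 6)
  fwd <- occ[occ$strand == "+", ]
  expect_equal(fwd$start, 3L)
  expect_equal(fwd$end, 9L)
  expect_equal(fwd$word, "ACGTAC")

  # worked overlap pair: AGCTAG then GCTAGC spells AGCTAGC
  seqs2 <- Biostrings::DNAStringSet(c(s1 = "AGCTAGC"))
  gc2 <- make_digraph(
    data.frame(id = c("C001", "C002"), seed = c("AGCTAG", "GCTAGC"),
               f = c(2, 1), n_members = 1),
    list(C001 = "AGCTAG", C002 = "GCTAGC"),
    data.frame(from = "C001", to = "C002", w = 1), 6)
  occ2 <- collect_occurrences(c("C001", "C002"), gc2, seqs2, 6)
  expect_equal(nrow(occ2[occ2$strand == "+", ]), 1L)
  expect_equal(occ2$end[1] - occ2$start[1], 7L)
  expect_equal(occ2$word[occ2$strand == "+"], "AGCTAGC")
})

test_that("occurrence scan equals the exhaustive window oracle", {
  set.seed(6)
  strs <- stats::setNames(replicate(6, random_dna(50)), sprintf("s%d", 1:6))
  seqs <- Biostrings::DNAStringSet(strs)
  k <- 3
  observed <- unique(iter_kmers(seqs, k, both_strands = TRUE)$kmer)
  members <- list(C001 = sample(observed, 14), C002 = sample(observed, 14))
  gc_graph <- make_digraph(
    data.frame(id = c("C001", "C002"), seed = c("AAA", "CCC"), f = c(2, 1),
               n_members = 14),
    members,
    data.frame(from = "C001", to = "C002", w = 1), k)
  occ <- collect_occurrences(c("C001", "C002"), gc_graph, seqs, k)
  oracle <- oracle_occurrences(members, as.list(strs), k)
  expect_equal(sort_occ(occ), sort_occ(oracle))
})

test_that("refinement branches on the overlap ratio with exact boundaries", {
  o1 <- occ_df("s1", seq(0, 90, by = 10))                 # 10 occurrences
  make_o2 <- function(n_overlap) {
    # n_overlap coincide exactly with o1; the rest sit on another sequence
    rbind(occ_df("s1", seq(0, length.out = n_overlap, by = 10)),
          occ_df("s2", seq(0, length.out = 8 - n_overlap, by = 10)))
  }
  path <- structure(list(vertices = c("C001", "C002"), start = "C001",
                         upstream = "C001", downstream = c("C001", "C002")),
                    class = "motif_path")
  full <- occ_df("s1", c(0, 20))

  res_hi <- refine_motifs(path, o1, make_o2(6), full)     # r = 6/8 > 1/2
  expect_length(res_hi, 1)
  expect_equal(res_hi[[1]]$source, "full_path")

  res_mid <- refine_motifs(path, o1, make_o2(3), full)    # r = 3/8
  expect_length(res_mid, 3)
  expect_setequal(vapply(res_mid, `[[`, character(1), "source"),
                  c("upstream", "downstream", "intersection"))

  res_lo <- refine_motifs(path, o1, make_o2(2), full)     # r = 2/8 = 1/4
  expect_length(res_lo, 2)

  res_half <- refine_motifs(path, o1, make_o2(4), full)   # r = 4/8 = 1/2
  expect_length(res_half, 3)

  # empty side behaves as r = 0 and empty sets are dropped
  res_empty <- refine_motifs(path, o1, o1[0, ], full)
  expect_length(res_empty, 1)
  expect_equal(res_empty[[1]]$source, "upstream")
})

test_that("build_pwm tallies columns, ties resolve A<C<G<T", {
  occ <- data.frame(seqname = "s", start = 0, end = 3, strand = "+",
                    word = c("ACG", "ACG", "ACG", "ACG"),
                    stringsAsFactors = FALSE)
  m <- build_pwm(occ, pseudocount = 0)
  expect_equal(m$consensus, "ACG")
  expect_equal(m$pwm[, 1], c(A = 1, C = 0, G = 0, T = 0))

  occ2 <- data.frame(seqname = "s", start = 0, end = 2, strand = "+",
                     word = c("AA", "AC"), stringsAsFactors = FALSE)
  m2 <- build_pwm(occ2, pseudocount = 0)
  expect_equal(unname(m2$pwm[, 2]), c(0.5, 0.5, 0, 0))
  expect_equal(m2$consensus, "AA")

  set.seed(11)
  words <- replicate(10, random_dna(5))
  occ3 <- data.frame(seqname = "s", start = 0, end = 5, strand = "+",
                     word = words, stringsAsFactors = FALSE)
  m3 <- build_pwm(occ3, pseudocount = 0.25)
  expect_equal(unname(colSums(m3$pwm)), rep(1, 5), tolerance = 1e-9)
  for (j in 1:5) {
    tallies <- table(factor(substr(words, j, j), levels = c("A", "C", "G", "T")))
    expect_equal(unname(m3$pwm[, j]),
                 unname((as.numeric(tallies) + 0.25) / (10 + 1)))
  }
  expect_error(build_pwm(occ3[0, ]), "zero occurrences")
})

test_that("MEME and BED outputs carry every motif and site", {
  set.seed(12)
  words <- replicate(6, random_dna(7))
  occ <- data.frame(seqname = sprintf("s%d", 1:6), start = 2, end = 9,
                    strand = "+", word = words, stringsAsFactors = FALSE)
  motifs <- list(motif_a = build_pwm(occ))
  meme <- withr::local_tempfile(fileext = ".meme")
  write_meme(motifs, meme)
  lines <- readLines(meme)
  expect_true(any(grepl("^MEME version", lines)))
  expect_true(any(grepl("^MOTIF motif_a", lines)))
  expect_true(any(grepl("w= 7 nsites= 6", lines)))

  bed <- withr::local_tempfile(fileext = ".bed")
  write_sites_bed(motifs, bed)
  sites <- utils::read.delim(bed, header = FALSE, stringsAsFactors = FALSE)
  expect_equal(nrow(sites), 6L)
  expect_true(all(sites$V5 >= 0 & sites$V5 <= 1000))
})
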