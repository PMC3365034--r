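test_that("k-mer seeding finds sharing pairs and misses saturated divergence", {
  # identical sequences share all k-mers
  s <- random_dna(1, 36)
  p <- kmer_candidate_pairs(c(s, s), k = 11)
  expect_identical(nrow(p), 1L)
  # a difference every 5th base leaves no intact 11-mer
  a <- strrep("A", 36)
  bc <- strsplit(a, "")[[1]]
  bc[seq(1, 36, by = 5)] <- "C"
  p2 <- kmer_candidate_pairs(c(a, paste(bc, collapse = "")), k = 11)
  expect_identical(nrow(p2), 0L)
})

test_that("pigeonhole: 36-mers with two mismatches always share an 11-mer", {
  set.seed(501)
  base <- random_dna(1, 36)
  positions <- utils::combn(36, 2)
  for (col in seq_len(ncol(positions))) {
    mut <- strsplit(base, "")[[1]]
    for (p in positions[, col])
      mut[p] <- setdiff(c("A", "C", "G", "T"), mut[p])[1]
    pairs <- kmer_candidate_pairs(c(base, paste(mut, collapse = "")), k = 11)
    expect_identical(nrow(pairs), 1L)
  }
})

test_that("global alignment identity matches hand counts and a DP oracle", {
  s <- random_dna(1, 36)
  expect_equal(pairwise_align(s, s)$identity, 1.0)
  # three substitutions in 36 bp
  mut <- strsplit(s, "")[[1]]
  for (p in c(5, 15, 25)) mut[p] <- setdiff(c("A", "C", "G", "T"), mut[p])[1]
  al <- pairwise_align(s, paste(mut, collapse = ""))
  expect_equal(al$identity, 33 / 36, tolerance = 1e-12)
  expect_identical(al$aligned_length, 36L)
  # a single 1 bp deletion
  del <- paste(strsplit(s, "")[[1]][-18], collapse = "")
  al2 <- pairwise_align(s, del)
  expect_equal(al2$identity, 35 / 36, tolerance = 1e-12)
  expect_identical(sum(strsplit(al2$transcript, "")[[1]] == "D"), 1L)
  expect_error(pairwise_align("", s))
})

test_that("alignment scores agree with an independent aligner on random pairs", {
  set.seed(502)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  for (rep in 1:20) {
    a <- random_dna(1, sample(20:40, 1))
    b <- random_dna(1, sample(20:40, 1))
    ours <- pairwise_align(a, b)
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 2)
    expect_equal(ours$score, Biostrings::score(ref))
  }
})

test_that("similarity graph keeps intra-locus haplotypes and drops background", {
  s <- random_dna(1, 36)
  # identical pair: one edge of weight 1
  g <- build_similarity_graph(c(s, s))
  expect_identical(nrow(g$edges), 1L)
  expect_equal(g$edges$weight, 1.0)
  # 4 SNPs in 36 bp (~89% identity): edge retained at the 0.80 floor,
  # even though single-mismatch stacking heuristics would separate them
  # (an intact 11-mer seed must survive, as with any seeded aligner)
  mut <- strsplit(s, "")[[1]]
  for (p in c(2, 5, 30, 34)) mut[p] <- setdiff(c("A", "C", "G", "T"), mut[p])[1]
  g4 <- build_similarity_graph(c(s, paste(mut, collapse = "")))
  expect_identical(nrow(g4$edges), 1L)
  expect_gte(g4$edges$weight, 0.80)
  # unrelated random sequences (~60% alignable identity): no edge
  set.seed(503)
  g0 <- build_similarity_graph(random_dna(6, 36))
  expect_identical(nrow(g0$edges), 0L)
})

test_that("reverse-complement haplotypes are detected and flagged", {
  s <- random_dna(1, 36)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  g <- build_similarity_graph(c(s, rc), check_rc = TRUE)
  expect_identical(nrow(g$edges), 1L)
  expect_identical(g$edges$orientation, "RC")
  g_off <- build_similarity_graph(c(s, rc), check_rc = FALSE)
  expect_identical(nrow(g_off$edges), 0L)
})

test_that("MCL reproduces connected components on separable graphs", {
  set.seed(504)
  # random block graph: 4 components of sizes 2-6, no inter-edges
  sizes <- c(2, 4, 5, 6)
  offs <- cumsum(c(0, sizes))
  edges <- do.call(rbind, lapply(seq_along(sizes), function(b) {
    ids <- offs[b] + seq_len(sizes[b])
    p <- t(utils::combn(ids, 2))
    p[stats::runif(nrow(p)) < 0.8 | seq_len(nrow(p)) == 1, , drop = FALSE]
  }))
  gr <- graph_from_edges(sum(sizes), edges[, 1], edges[, 2],
                         stats::runif(nrow(edges), 0.85, 1))
  cl <- mcl_cluster(gr)
  # partition invariants
  expect_identical(sort(unlist(cl$clusters)), seq_len(sum(sizes)))
  # no cluster spans components
  blk <- rep(seq_along(sizes), sizes)
  for (members in cl$clusters)
    expect_identical(length(unique(blk[members])), 1L)
})

test_that("MCL splits the bridged two-clique fixture and matches a dense oracle", {
  gr <- two_clique_graph(0.1)
  cl <- mcl_cluster(gr, inflation = 2.0)
  expect_identical(canon_clusters(cl$clusters), list(1:5, 6:10))
  # independent naive dense-matrix iteration agrees
  adj <- matrix(0, 10, 10)
  for (r in seq_len(nrow(gr$edges))) {
    adj[gr$edges$i[r], gr$edges$j[r]] <- gr$edges$weight[r]
    adj[gr$edges$j[r], gr$edges$i[r]] <- gr$edges$weight[r]
  }
  expect_identical(canon_clusters(naive_mcl(adj, inflation = 2)),
                   canon_clusters(cl$clusters))
  # a single clique is one cluster
  p <- expand.grid(i = 1:5, j = 1:5); p <- p[p$i < p$j, ]
  g1 <- graph_from_edges(5, p$i, p$j, rep(1, nrow(p)))
  expect_identical(length(mcl_cluster(g1)$clusters), 1L)
})

test_that("higher inflation never coarsens the two-clique fixture", {
  gr <- two_clique_graph(0.1)
  n_cl <- vapply(c(1.5, 2, 4, 6), function(inf)
    length(mcl_cluster(gr, inflation = inf)$clusters), integer(1))
  expect_true(all(diff(n_cl) >= 0))
})
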