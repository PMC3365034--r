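# Independent oracles and fixture builders shared across tests.

# Naive dense-matrix Markov clustering, written directly from the
# algorithm definition, independent of the package's sparse per-component
# implementation.
naive_mcl <- function(adj, inflation = 2, expansion = 2, prune = 1e-5,
                      tol = 1e-6, max_iter = 100) {
  diag(adj) <- 1
  norm <- function(M) sweep(M, 2, pmax(colSums(M), .Machine$double.eps), "/")
  M <- norm(adj)
  for (it in seq_len(max_iter)) {
    Mprev <- M
    P <- M
    for (e in seq_len(expansion - 1)) P <- P %*% M
    P <- P^inflation
    P[P < prune] <- 0
    M <- norm(P)
    if (max(abs(M - Mprev)) < tol) break
  }
  S <- (M + t(M)) > 0
  diag(S) <- FALSE
  n <- nrow(S)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in which(S[i, ])) {
      m <- min(comp[i], comp[j])
      if (comp[i] != m || comp[j] != m) { comp[i] <- comp[j] <- m; changed <- TRUE }
    }
    if (!changed) break
  }
  unname(split(seq_len(n), comp))
}

# similarity_graph from an explicit edge table
graph_from_edges <- function(n, i, j, w) {
  structure(list(n = n,
                 edges = data.frame(i = i, j = j, weight = w,
                                    orientation = "F")),
            class = "similarity_graph")
}

# canonical form of a clustering for comparison
canon_clusters <- function(cl) {
  cl <- lapply(cl, sort)
  cl[order(vapply(cl, min, numeric(1)))]
}

# two 5-cliques joined by a single weak edge
two_clique_graph <- function(bridge_weight = 0.1) {
  p <- expand.grid(i = 1:5, j = 1:5)
  p <- p[p$i < p$j, ]
  graph_from_edges(10,
                   c(p$i, p$i + 5, 5L),
                   c(p$j, p$j + 5, 6L),
                   c(rep(1, 2 * nrow(p)), bridge_weight))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

mutate_seq <- function(seq, n_snp = 0, del_at = NULL, ins_at = NULL,
                       ins_seq = "") {
  chars <- strsplit(seq, "")[[1]]
  if (n_snp > 0) {
    pos <- sample(seq_along(chars), n_snp)
    for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  if (!is.null(ins_at))
    chars <- append(chars, strsplit(ins_seq, "")[[1]], after = ins_at)
  if (!is.null(del_at))
    chars <- chars[-(del_at:(del_at + attr(del_at, "len") %||% 1 - 1))]
  paste(chars, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built uniq_set from sequences / counts matrix
make_uniq <- function(seqs, counts, qual = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
  if (is.null(qual))
    qual <- lapply(nchar(seqs), function(L) rep(30, L))
  structure(list(sequence = seqs, counts = counts,
                 total = as.integer(rowSums(counts)), qual = qual,
                 pairs = NULL),
            class = "uniq_set")
}

# small end-to-end simulation shared by pipeline-level tests
small_sim <- function(seed = 42, genome_bp = 2e5, n_samples = 4,
                      reads_per_sample = 4000, per_base_error = 0.002,
                      snp_rate = 0.001) {
  g <- make_genome(genome_bp, 0.42, seed = seed)
  samp <- derive_samples(g, n_samples, snp_rate = snp_rate, seed = seed + 1)
  simulate_library(samp, "EcoRI", "MspI", size_selection_model(300, 25),
                   reads_per_sample = reads_per_sample,
                   per_base_error = per_base_error, seed = seed + 2)
}
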