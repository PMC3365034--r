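# all unordered pairs from a sorted vector of node ids, as a numeric key
# key = (i-1)*n + (j-1) with i < j
bucket_pair_keys <- function(b, n) {
  b <- sort(unique(b))
  m <- length(b)
  if (m < 2L) return(numeric(0))
  cnt <- m - seq_len(m - 1L)
  i <- rep(b[seq_len(m - 1L)], cnt)
  j <- b[sequence(cnt) + rep(seq_len(m - 1L), cnt)]
  (i - 1) * n + (j - 1)
}

#' Candidate sequence pairs sharing exact k-mers
#'
#' Seed step replacing an external all-vs-all aligner: only pairs of
#' unique sequences sharing at least `min_shared` exact k-mers are
#' aligned. By the pigeonhole principle, two length-36 sequences with at
#' most two mismatches always share an 11-mer, so the default seed misses
#' no pair at or above ~90% identity on reads of 36 bp or more.
#'
#' @param seqs Character vector of sequences (or a `uniq_set`).
#' @param k Seed k-mer length (default 11).
#' @param min_shared Minimum number of shared distinct k-mers.
#' @return Two-column integer matrix of candidate index pairs (i < j).
#' @export
kmer_candidate_pairs <- function(seqs, k = 11L, min_shared = 1L) {
  if (inherits(seqs, "uniq_set")) seqs <- seqs$sequence
  n <- length(seqs)
  if (n < 2L) return(matrix(integer(0), ncol = 2,
                            dimnames = list(NULL, c("i", "j"))))
  km <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1L), k:L))
  })
  buckets <- split(rep(seq_len(n), lengths(km)), unlist(km))
  keys <- unlist(lapply(buckets, bucket_pair_keys, n = n), use.names = FALSE)
  if (length(keys) == 0L) return(matrix(integer(0), ncol = 2,
                                        dimnames = list(NULL, c("i", "j"))))
  r <- rle(sort(keys))
  keep <- r$values[r$lengths >= min_shared]
  cbind(i = as.integer(keep %/% n) + 1L,
        j = as.integer(keep %% n) + 1L)
}

#' Global pairwise alignment of two sequences
#'
#' Needleman-Wunsch global alignment with linear gap penalty (defaults:
#' match +1, mismatch -1, gap -2). Identity is the fraction of alignment
#' columns that are matches, so both mismatches and gap columns dilute
#' it — this makes the similarity measure read-length invariant.
#'
#' @param a,b Sequences (character scalars).
#' @param match,mismatch,gap Scoring parameters.
#' @return List with `identity`, `aligned_length` (columns), `score`,
#'   `transcript` (M/D/I operations, a as reference), and the two gapped
#'   `alignment` strings.
#' @examples
#' pairwise_align("ACGTACGT", "ACGTTACGT")$identity
#' @export
pairwise_align <- function(a, b, match = 1L, mismatch = -1L, gap = -2L) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  r <- .nw_pair(a, b, match, mismatch, gap)
  ops <- strsplit(r$transcript, "")[[1]]
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  arow <- character(length(ops)); brow <- character(length(ops))
  ia <- 0L; ib <- 0L
  for (p in seq_along(ops)) {
    if (ops[p] != "I") { ia <- ia + 1L; arow[p] <- ac[ia] } else arow[p] <- "-"
    if (ops[p] != "D") { ib <- ib + 1L; brow[p] <- bc[ib] } else brow[p] <- "-"
  }
  list(identity = r$identity, aligned_length = r$columns, score = r$score,
       transcript = r$transcript,
       alignment = c(paste(arow, collapse = ""), paste(brow, collapse = "")))
}

#' Build the all-vs-all similarity graph over unique sequences
#'
#' Aligns every k-mer candidate pair and keeps an undirected edge when the
#' alignment identity reaches `min_identity` (default 0.80 — deliberately
#' permissive so that multi-SNP and indel-bearing haplotypes of one locus
#' stay connected, while the ~60% identity background between unrelated
#' loci stays far below the floor). Edge weight is the identity. When
#' `check_rc` is set, reverse-complement candidate hits are also aligned;
#' an RC edge is flagged with `orientation = "RC"` and scored on the
#' oriented pair.
#'
#' @param uniq A `uniq_set` or a character vector of sequences.
#' @param min_identity Identity floor for an edge.
#' @param k,min_shared Seed parameters (see [kmer_candidate_pairs()]).
#' @param check_rc Also detect reverse-complement similarity.
#' @param match,mismatch,gap Alignment scoring.
#' @return Object of class `similarity_graph`: `n` nodes and an `edges`
#'   data.frame (i, j, weight, orientation).
#' @export
build_similarity_graph <- function(uniq, min_identity = 0.80, k = 11L,
                                   min_shared = 1L, check_rc = TRUE,
                                   match = 1L, mismatch = -1L, gap = -2L) {
  seqs <- if (inherits(uniq, "uniq_set")) uniq$sequence else uniq
  n <- length(seqs)
  cand <- kmer_candidate_pairs(seqs, k = k, min_shared = min_shared)
  edges <- data.frame(i = integer(0), j = integer(0), weight = numeric(0),
                      orientation = character(0))
  if (nrow(cand) > 0L) {
    al <- .nw_batch(seqs, cand[, "i"], cand[, "j"], match, mismatch, gap)
    keep <- al$identity >= min_identity
    edges <- data.frame(i = al$i[keep], j = al$j[keep],
                        weight = al$identity[keep],
                        orientation = rep("F", sum(keep)))
  }
  if (check_rc && n >= 2L) {
    rc <- revcomp(seqs)
    # candidate (i, rc j): bucket forward and rc k-mers together; keep
    # only mixed pairs, mapped back to original ids
    both <- kmer_candidate_pairs(c(seqs, rc), k = k, min_shared = min_shared)
    mixed <- both[both[, "i"] <= n & both[, "j"] > n, , drop = FALSE]
    if (nrow(mixed) > 0L) {
      i <- mixed[, "i"]; j <- mixed[, "j"] - n
      ok <- i != j
      i <- pmin(i[ok], j[ok]); j2 <- pmax(mixed[ok, "i"], mixed[ok, "j"] - n)
      key <- unique((i - 1) * n + (j2 - 1))
      i <- as.integer(key %/% n) + 1L; j2 <- as.integer(key %% n) + 1L
      if (length(i) > 0L) {
        al <- .nw_batch(c(seqs, rc), i, j2 + n, match, mismatch, gap)
        keep <- al$identity >= min_identity
        if (any(keep)) {
          rc_edges <- data.frame(i = i[keep], j = j2[keep],
                                 weight = al$identity[keep],
                                 orientation = rep("RC", sum(keep)))
          # keep the better of F/RC for a pair present in both
          all_e <- rbind(edges, rc_edges)
          key2 <- (all_e$i - 1) * n + (all_e$j - 1)
          ord <- order(key2, -all_e$weight)
          all_e <- all_e[ord, , drop = FALSE]
          edges <- all_e[!duplicated(key2[ord]), , drop = FALSE]
          rownames(edges) <- NULL
        }
      }
    }
  }
  structure(list(n = n, edges = edges), class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph> %d nodes, %d edges\n", x$n, nrow(x$edges)))
  invisible(x)
}

#' Write a similarity graph as a TSV edge list
#' @param graph A `similarity_graph`.
#' @param path File path.
#' @export
write_edge_list <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# one MCL run on a (small) symmetric sparse adjacency matrix;
# returns list of integer vectors of local node indices
mcl_core <- function(A, inflation, expansion, prune, tol, max_iter,
                     self_loop = 1) {
  m <- nrow(A)
  Matrix::diag(A) <- self_loop
  normalize <- function(M) {
    cs <- Matrix::colSums(M)
    cs[cs == 0] <- 1
    M %*% Matrix::Diagonal(x = 1 / cs)
  }
  M <- normalize(A)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Mprev <- M
    for (e in seq_len(expansion - 1L)) M <- M %*% Mprev  # matrix power
    M@x <- M@x^inflation
    M@x[M@x < prune] <- 0
    M <- Matrix::drop0(M)
    M <- normalize(M)
    if (max(abs(M - Mprev)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within max_iter; returning current state")
  # clusters = connected components of the converged matrix support
  S <- (M + Matrix::t(M)) > 0
  g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  lapply(unname(split(seq_len(m), comp)), unname)
}

#' Markov clustering of a similarity graph
#'
#' Partitions the similarity graph into putative ortholog groups with the
#' Markov Cluster algorithm: the column-stochastic weighted adjacency
#' (uniform self-loops added) is alternately expanded (matrix power) and
#' inflated (elementwise power + renormalisation, with pruning of tiny
#' entries) until the flow matrix stabilises; clusters are read off the
#' attractor structure. Disconnected components can never merge, so MCL
#' is run independently per connected component. Extraction order is
#' deterministic (clusters sorted by their smallest node id).
#'
#' @param graph A `similarity_graph` (or an edge data.frame plus `n`).
#' @param inflation Inflation exponent (granularity; default 2.0).
#' @param expansion Expansion power (default 2).
#' @param prune Entries below this are dropped after inflation.
#' @param tol Convergence tolerance on the max entry change.
#' @param max_iter Iteration cap; non-convergence returns the current
#'   state with a warning.
#' @return Object of class `mcl_clusters`: list `clusters` of integer
#'   node-id vectors (disjoint, covering all nodes) and a `membership`
#'   integer vector.
#' @export
mcl_cluster <- function(graph, inflation = 2.0, expansion = 2L,
                        prune = 1e-5, tol = 1e-6, max_iter = 100L) {
  n <- graph$n
  edges <- graph$edges
  membership <- integer(n)
  clusters <- list()
  if (nrow(edges) > 0L) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges$i, to = edges$j),
      directed = FALSE, vertices = data.frame(name = seq_len(n)))
    comp <- igraph::components(g)$membership
    comp <- unname(comp[as.character(seq_len(n))])
  } else {
    comp <- seq_len(n)
  }
  for (cid in sort(unique(comp))) {
    nodes <- which(comp == cid)
    if (length(nodes) == 1L) {
      clusters[[length(clusters) + 1L]] <- nodes
      next
    }
    sub <- edges[edges$i %in% nodes & edges$j %in% nodes, , drop = FALSE]
    li <- match(sub$i, nodes); lj <- match(sub$j, nodes)
    A <- Matrix::sparseMatrix(i = c(li, lj), j = c(lj, li),
                              x = c(sub$weight, sub$weight),
                              dims = c(length(nodes), length(nodes)))
    cl <- mcl_core(A, inflation, expansion, prune, tol, max_iter)
    for (loc in cl) clusters[[length(clusters) + 1L]] <- unname(nodes[loc])
  }
  clusters <- lapply(clusters, sort)
  clusters <- clusters[order(vapply(clusters, min, numeric(1)))]
  for (ci in seq_along(clusters)) membership[clusters[[ci]]] <- ci
  structure(list(clusters = clusters, membership = membership),
            class = "mcl_clusters")
}

#' @export
print.mcl_clusters <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("<mcl_clusters> %d clusters over %d nodes (max size %d)\n",
              length(x$clusters), length(x$membership), max(sizes)))
  invisible(x)
}

#' Write clusters as a TSV table
#' @param clusters An `mcl_clusters` object.
#' @param path File path.
#' @export
write_cluster_table <- function(clusters, path) {
  tab <- data.frame(
    cluster_id = rep(seq_along(clusters$clusters),
                     lengths(clusters$clusters)),
    member = unlist(clusters$clusters))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
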