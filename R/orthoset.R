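#' Expected fraction of reads containing at least one error
#'
#' Linear approximation `100 * L * e` (percent) for the fraction of
#' length-L reads carrying a sequencing error at per-base error rate e,
#' together with the exact value `100 * (1 - (1 - e)^L)`. This is the
#' calculation that motivates the 10% ploidy-filter threshold for ~31 bp
#' reads at per-base error rates of a few per mille.
#'
#' @param read_length Read length L (bp).
#' @param per_base_error Per-base error rate e in `[0, 1]`.
#' @return Named numeric vector `c(linear_pct, exact_pct)`.
#' @examples
#' expected_error_read_fraction(31, 0.001)  # 3.1% linear
#' @export
expected_error_read_fraction <- function(read_length, per_base_error) {
  if (per_base_error < 0 || per_base_error > 1)
    stop("per_base_error must lie in [0, 1]")
  c(linear_pct = 100 * read_length * per_base_error,
    exact_pct = 100 * (1 - (1 - per_base_error)^read_length))
}

#' Ploidy-aware paralog/repeat filter for one cluster
#'
#' For each individual with enough reads in the cluster, computes the
#' fraction of its reads belonging to unique sequences beyond the
#' `ploidy` most frequent ones for that individual (the "non-first-two"
#' fraction in a diploid). The cluster is discarded iff any evaluated
#' individual's fraction strictly exceeds `max_fraction`: a legitimate
#' single-copy locus can only exceed it through an implausible error
#' load, whereas a cluster collapsing two loci shows the second locus's
#' haplotypes as excess sequences. Individuals with fewer than
#' `min_reads` reads are not evaluated (a single error read among 3
#' would spuriously exceed 10%).
#'
#' @param counts Integer matrix (unique sequences x samples) of
#'   per-individual observation counts within the cluster.
#' @param ploidy Organism ploidy p (default 2): reads beyond the top p
#'   unique sequences count as excess.
#' @param max_fraction Discard threshold f (default 0.10; a fraction of
#'   exactly f is retained, only "> f" discards).
#' @param min_reads Minimum reads for an individual to be evaluated.
#' @return List with `verdict` (`"retained"`/`"discarded"`), `fractions`
#'   (per individual; NA when not evaluated), and `evaluated` (logical).
#' @examples
#' ploidy_filter(matrix(c(45, 45, 10), ncol = 1))  # exactly 10%: retained
#' @export
ploidy_filter <- function(counts, ploidy = 2L, max_fraction = 0.10,
                          min_reads = 5L) {
  counts <- as.matrix(counts)
  if (length(counts) == 0L || sum(counts) == 0L)
    stop("empty cluster: no read counts to filter")
  totals <- colSums(counts)
  frac <- rep(NA_real_, ncol(counts))
  names(frac) <- colnames(counts)
  evaluated <- totals >= min_reads
  for (s in which(evaluated)) {
    top <- sum(sort(counts[, s], decreasing = TRUE)[seq_len(min(ploidy, nrow(counts)))])
    frac[s] <- (totals[s] - top) / totals[s]
  }
  verdict <- if (any(frac[evaluated] > max_fraction)) "discarded" else "retained"
  list(verdict = verdict, fractions = frac, evaluated = evaluated)
}

#' Choose the pseudo-reference member of a cluster
#'
#' The pseudo-reference is the most highly represented of the set of
#' longest member sequences: restrict to maximal length, then maximal
#' total count, ties broken by lexicographically smallest sequence.
#'
#' @param seqs Member sequences.
#' @param total_counts Total observation count per member.
#' @return Index of the chosen member.
#' @export
choose_pseudoreference <- function(seqs, total_counts) {
  stopifnot(length(seqs) >= 1L, length(seqs) == length(total_counts))
  lens <- nchar(seqs)
  cand <- which(lens == max(lens))
  cand <- cand[total_counts[cand] == max(total_counts[cand])]
  cand[order(seqs[cand])][1]
}

#' Progressive multiple alignment of cluster members
#'
#' Center-star progressive alignment: members are ordered by descending
#' total count then length; every other member is globally aligned to the
#' first (the center) with the same scoring as graph construction, and
#' the pairwise alignments are merged into one column matrix under
#' "once a gap, always a gap" semantics (an insertion column opened by
#' any member stays open for all rows).
#'
#' @param seqs Member sequences.
#' @param total_counts Total count per member (guide order; defaults to
#'   equal).
#' @param match,mismatch,gap Alignment scoring.
#' @return Character matrix (members x columns) of the gapped alignment;
#'   rows in the input order of `seqs`.
#' @export
align_cluster <- function(seqs, total_counts = rep(1L, length(seqs)),
                          match = 1L, mismatch = -1L, gap = -2L) {
  stopifnot(length(seqs) >= 1L)
  n <- length(seqs)
  if (n == 1L)
    return(matrix(strsplit(seqs, "")[[1]], nrow = 1))
  guide <- order(-total_counts, -nchar(seqs), seqs)
  center <- guide[1]
  cseq <- seqs[center]
  Lc <- nchar(cseq)
  others <- guide[-1]
  # transcript of center (a) vs member (b) for every non-center member
  trs <- lapply(others, function(m)
    strsplit(.nw_pair(cseq, seqs[m], match, mismatch, gap)$transcript, "")[[1]])
  # insertion run lengths before center position p+1 (slots 0..Lc)
  ins_runs <- lapply(trs, function(ops) {
    runs <- integer(Lc + 1L)
    p <- 0L; run <- 0L
    for (op in ops) {
      if (op == "I") run <- run + 1L
      else {
        runs[p + 1L] <- runs[p + 1L] + run; run <- 0L
        p <- p + 1L
      }
    }
    runs[Lc + 1L] <- runs[Lc + 1L] + run
    runs
  })
  ins <- Reduce(pmax, ins_runs, accumulate = FALSE,
                init = integer(Lc + 1L))
  W <- Lc + sum(ins)
  msa <- matrix("-", nrow = n, ncol = W)
  # column index of center base p and start of insertion slot p
  slot_start <- cumsum(c(1L, ins[seq_len(Lc)] + 1L))  # length Lc+1
  center_col <- slot_start[seq_len(Lc)] + ins[seq_len(Lc)]
  msa[center, center_col] <- strsplit(cseq, "")[[1]]
  for (t in seq_along(others)) {
    m <- others[t]
    bc <- strsplit(seqs[m], "")[[1]]
    ops <- trs[[t]]
    row <- rep("-", W)
    p <- 0L; ib <- 0L; run <- 0L
    for (op in ops) {
      if (op == "I") {
        ib <- ib + 1L
        row[slot_start[p + 1L] + run] <- bc[ib]  # left-aligned in the slot
        run <- run + 1L
      } else {
        run <- 0L
        p <- p + 1L
        if (op == "M") { ib <- ib + 1L; row[center_col[p]] <- bc[ib] }
      }
    }
    msa[m, ] <- row
  }
  msa
}

# collapse an op-per-column vector into a CIGAR string
ops_to_cigar <- function(ops) {
  if (length(ops) == 0L) return("*")
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

#' Parse a CIGAR into consumed read length and reference span
#'
#' @param cigar CIGAR string (M/I/D operations).
#' @return List `read_len` (M + I) and `ref_span` (M + D).
#' @export
cigar_lengths <- function(cigar) {
  m <- gregexpr("(\\d+)([MID])", cigar)[[1]]
  parts <- regmatches(cigar, gregexpr("(\\d+)([MID])", cigar))[[1]]
  lens <- as.integer(sub("[MID]$", "", parts))
  ops <- sub("^\\d+", "", parts)
  list(read_len = sum(lens[ops %in% c("M", "I")]),
       ref_span = sum(lens[ops %in% c("M", "D")]))
}

# POS (1-based) and CIGAR of one MSA row against the reference row
row_to_cigar <- function(ref_row, read_row) {
  has_read <- read_row != "-"
  if (!any(has_read)) return(NULL)
  first <- which(has_read)[1]
  last <- max(which(has_read))
  pos <- sum(ref_row[seq_len(first - 1L)] != "-") + 1L
  cols <- first:last
  rr <- ref_row[cols] != "-"
  dd <- read_row[cols] != "-"
  ops <- ifelse(rr & dd, "M", ifelse(dd, "I", ifelse(rr, "D", "")))
  ops <- ops[ops != ""]
  list(pos = pos, cigar = ops_to_cigar(ops))
}

#' Build ortholog sets from clusters
#'
#' Applies the ploidy-aware filter to every cluster, chooses a
#' pseudo-reference for retained clusters, and computes the per-cluster
#' multiple alignment plus per-member POS/CIGAR against the
#' pseudo-reference.
#'
#' @param uniq A `uniq_set`.
#' @param clusters An `mcl_clusters` object (or list of index vectors).
#' @param ploidy,max_fraction,min_reads Filter parameters (see
#'   [ploidy_filter()]).
#' @param align_discarded Also compute MSAs for discarded clusters
#'   (default FALSE).
#' @return List of class `ortholog_sets`; each element has `cluster_id`,
#'   `members`, `verdict`, `fractions`, and for retained clusters
#'   `pseudo_ref` (member index), `ref_seq`, `msa`, `pos`, `cigar`.
#' @export
build_ortholog_sets <- function(uniq, clusters, ploidy = 2L,
                                max_fraction = 0.10, min_reads = 5L,
                                align_discarded = FALSE) {
  cl <- if (inherits(clusters, "mcl_clusters")) clusters$clusters else clusters
  sets <- vector("list", length(cl))
  for (ci in seq_along(cl)) {
    members <- cl[[ci]]
    counts <- uniq$counts[members, , drop = FALSE]
    flt <- ploidy_filter(counts, ploidy = ploidy,
                         max_fraction = max_fraction, min_reads = min_reads)
    set <- list(cluster_id = sprintf("cluster_%05d", ci),
                members = members,
                verdict = flt$verdict,
                fractions = flt$fractions)
    if (flt$verdict == "retained" || align_discarded) {
      seqs <- uniq$sequence[members]
      totals <- uniq$total[members]
      pr <- choose_pseudoreference(seqs, totals)
      msa <- align_cluster(seqs, totals)
      ref_row <- msa[pr, ]
      pc <- lapply(seq_len(nrow(msa)), function(r)
        row_to_cigar(ref_row, msa[r, ]))
      set$pseudo_ref <- pr
      set$ref_seq <- paste(ref_row[ref_row != "-"], collapse = "")
      set$msa <- msa
      set$pos <- vapply(pc, function(z) if (is.null(z)) NA_integer_ else z$pos,
                        integer(1))
      set$cigar <- vapply(pc, function(z) if (is.null(z)) NA_character_ else z$cigar,
                          character(1))
    }
    sets[[ci]] <- set
  }
  structure(sets, class = "ortholog_sets")
}

#' @export
print.ortholog_sets <- function(x, ...) {
  v <- vapply(x, `[[`, character(1), "verdict")
  cat(sprintf("<ortholog_sets> %d clusters: %d retained, %d discarded\n",
              length(x), sum(v == "retained"), sum(v == "discarded")))
  invisible(x)
}

#' Emit SAM records and pseudo-reference FASTA for retained clusters
#'
#' Each retained cluster contributes one @SQ line (name = cluster id,
#' LN = ungapped pseudo-reference length) and one FASTA record; each
#' sample contributes one @RG line. Every member observation expands to
#' `count` SAM records (default; genotypers weight by depth) or to a
#' single record carrying an `XC:i:count` tag. MAPQ is 255 (unavailable)
#' and FLAG 0: orientation was normalised during clustering. Qualities
#' are the per-position mean Phred values rounded at emission.
#'
#' @param sets An `ortholog_sets` object.
#' @param uniq The `uniq_set` the clusters index into.
#' @param sam_path Output SAM path.
#' @param fasta_path Output reference FASTA path.
#' @param expand Emit one record per observation (TRUE) or one per
#'   member/sample with a count tag (FALSE).
#' @param sample_metadata Optional data.frame with `sample_id` plus extra
#'   @RG fields (e.g. `library`).
#' @return Invisibly, a list with `n_records`, `n_clusters`, and the two
#'   paths.
#' @export
export_sam <- function(sets, uniq, sam_path, fasta_path, expand = TRUE,
                       sample_metadata = NULL) {
  samples <- colnames(uniq$counts)
  retained <- Filter(function(s) s$verdict == "retained", sets)
  hd <- "@HD\tVN:1.6\tSO:unsorted"
  sq <- vapply(retained, function(s)
    sprintf("@SQ\tSN:%s\tLN:%d", s$cluster_id, nchar(s$ref_seq)), character(1))
  rg <- vapply(samples, function(s)
    sprintf("@RG\tID:%s\tSM:%s", s, s), character(1))
  records <- character(0)
  n_rec <- 0L
  fasta <- character(0)
  for (set in retained) {
    fasta <- c(fasta, paste0(">", set$cluster_id), set$ref_seq)
    for (r in seq_along(set$members)) {
      if (is.na(set$pos[r])) next
      u <- set$members[r]
      seq <- uniq$sequence[u]
      qual <- intToUtf8(pmin(pmax(round(uniq$qual[[u]]), 0), 93) + 33L)
      for (s in samples) {
        cnt <- as.integer(uniq$counts[u, s])
        if (cnt == 0L) next
        base <- sprintf("%s\t0\t%s\t%d\t255\t%s\t*\t0\t0\t%s\t%s\tRG:Z:%s",
                        "%s", set$cluster_id, set$pos[r], set$cigar[r],
                        seq, qual, s)
        if (expand) {
          qn <- sprintf("%s_u%d_%s_%d", set$cluster_id, u, s, seq_len(cnt))
          records <- c(records, sprintf(base, qn))
          n_rec <- n_rec + cnt
        } else {
          qn <- sprintf("%s_u%d_%s", set$cluster_id, u, s)
          records <- c(records, paste0(sprintf(base, qn),
                                       sprintf("\tXC:i:%d", cnt)))
          n_rec <- n_rec + 1L
        }
      }
    }
  }
  writeLines(c(hd, sq, rg, records), sam_path)
  writeLines(fasta, fasta_path)
  invisible(list(n_records = n_rec, n_clusters = length(retained),
                 sam_path = sam_path, fasta_path = fasta_path))
}

#' Write the per-cluster filter report
#'
#' TSV with one row per cluster: id, member count, total reads, verdict,
#' and the worst (maximum) per-individual non-top-p fraction.
#'
#' @param sets An `ortholog_sets` object.
#' @param uniq The corresponding `uniq_set`.
#' @param path File path.
#' @export
write_cluster_report <- function(sets, uniq, path) {
  tab <- do.call(rbind, lapply(sets, function(s) {
    fr <- s$fractions[!is.na(s$fractions)]
    data.frame(cluster_id = s$cluster_id,
               n_members = length(s$members),
               n_reads = sum(uniq$total[s$members]),
               verdict = s$verdict,
               max_nontop_fraction = if (length(fr)) max(fr) else NA_real_)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
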