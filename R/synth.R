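#' Generate a random genome sequence
#'
#' I.i.d. bases at a specified GC fraction; reproducible under a seed.
#'
#' @param length Sequence length (bp).
#' @param gc_fraction Fraction of G+C bases (default 0.42, a typical
#'   vertebrate value).
#' @param seed Optional integer seed.
#' @return Character scalar genome sequence.
#' @export
make_genome <- function(length, gc_fraction = 0.42, seed = NULL) {
  if (length <= 0) stop("length must be > 0")
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

# apply substitutions (1-based positions) to a sequence
apply_substitutions <- function(seq, pos, alt) {
  if (length(pos) == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  chars[pos] <- alt
  paste(chars, collapse = "")
}

#' Derive diverged sample haplotypes from a genome
#'
#' Two study designs are emulated. `two_fixed_lines` plants homozygous
#' differences between two parental lines A and B at `snp_rate` per base
#' (the fixed-difference rate between diverged sister taxa, ~1e-3); the
#' first two samples are the purebred parents and the remaining samples
#' draw each of their two haplotypes independently from {A, B}
#' (recombination-free F2-like genotypes). `outbred_panmictic` plants
#' segregating variants with uniform allele frequencies and samples each
#' haplotype's alleles binomially.
#'
#' @param genome Character genome sequence (see [make_genome()]).
#' @param n_samples Number of diploid individuals.
#' @param snp_rate Per-base substitution rate between lines / variant
#'   density (default 0.001).
#' @param mode `"two_fixed_lines"` or `"outbred_panmictic"`.
#' @param seed Optional integer seed.
#' @return Object of class `ddrad_samples`: per-sample haplotype
#'   sequences, the planted `variants` table (pos, ref, alt, and in
#'   outbred mode freq), and the sample table.
#' @export
derive_samples <- function(genome, n_samples, snp_rate = 0.001,
                           mode = c("two_fixed_lines", "outbred_panmictic"),
                           seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(genome)
  n_var <- stats::rbinom(1, L, snp_rate)
  pos <- sort(sample.int(L, n_var))
  ref <- if (n_var > 0) substring(genome, pos, pos) else character(0)
  bases <- c("A", "C", "G", "T")
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1),
                USE.NAMES = FALSE)
  sample_id <- sprintf("S%02d", seq_len(n_samples))
  if (mode == "two_fixed_lines") {
    lineA <- genome
    lineB <- apply_substitutions(genome, pos, alt)
    hap_line <- matrix("A", nrow = n_samples, ncol = 2)
    if (n_samples >= 2L) hap_line[2, ] <- "B"
    if (n_samples > 2L)
      hap_line[3:n_samples, ] <- sample(c("A", "B"),
                                        2L * (n_samples - 2L), replace = TRUE)
    haplotypes <- lapply(seq_len(n_samples), function(i)
      c(if (hap_line[i, 1] == "A") lineA else lineB,
        if (hap_line[i, 2] == "A") lineA else lineB))
    variants <- data.frame(pos = pos, ref = ref, alt = alt)
    alt_carried <- hap_line == "B"
  } else {
    freq <- stats::runif(n_var)
    carried <- matrix(stats::rbinom(n_var * 2L * n_samples, 1,
                                    rep(freq, 2L * n_samples)) == 1,
                      nrow = n_var)
    haplotypes <- lapply(seq_len(n_samples), function(i) {
      vapply(1:2, function(h) {
        idx <- which(carried[, 2L * (i - 1L) + h])
        apply_substitutions(genome, pos[idx], alt[idx])
      }, character(1))
    })
    variants <- data.frame(pos = pos, ref = ref, alt = alt, freq = freq)
    alt_carried <- carried
    hap_line <- NULL
  }
  structure(list(mode = mode, genome = genome, n_samples = n_samples,
                 sample_id = sample_id, haplotypes = haplotypes,
                 hap_line = hap_line, variants = variants,
                 alt_carried = alt_carried),
            class = "ddrad_samples")
}

#' @export
print.ddrad_samples <- function(x, ...) {
  cat(sprintf("<ddrad_samples> %s: %d samples, %d planted variants on %g bp\n",
              x$mode, x$n_samples, nrow(x$variants), nchar(x$genome)))
  invisible(x)
}

# oriented AB fragments of one haplotype: read starts at the enzyme-A end.
# locus key is the genomic coordinate of the A cut, strand-tagged, so the
# same locus gets the same key on every haplotype (substitution variants
# preserve coordinates).
oriented_ab_fragments <- function(hapseq, enzymeA, enzymeB) {
  enzA <- get_enzyme(enzymeA)
  frags <- double_digest(hapseq, enzymeA, enzymeB)
  ab <- frags[frags$frag_class == "AB", , drop = FALSE]
  if (nrow(ab) == 0L) return(NULL)
  left_is_A <- ab$left_enzyme == enzA$name
  fseq <- substring(hapseq, ab$start + 1L, ab$end)
  fseq[!left_is_A] <- revcomp(fseq[!left_is_A])
  ab$read_template <- fseq
  ab$locus <- ifelse(left_is_A, paste0("F", ab$start), paste0("R", ab$end))
  ab
}

# inject iid substitution errors; returns list(reads, n_errors)
inject_errors <- function(reads, per_base_error, read_length) {
  n <- length(reads)
  if (per_base_error <= 0) return(list(reads = reads, n_errors = integer(n)))
  n_err <- stats::rbinom(n, read_length, per_base_error)
  hit <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (r in hit) {
    chars <- strsplit(reads[r], "")[[1]]
    p <- sample.int(length(chars), n_err[r])
    chars[p] <- vapply(chars[p], function(b) sample(setdiff(bases, b), 1),
                       character(1))
    reads[r] <- paste(chars, collapse = "")
  }
  list(reads = reads, n_errors = n_err)
}

#' Simulate a barcoded ddRAD sequencing library
#'
#' For every sample, reads are drawn multinomially over the
#' size-selection weights of that sample's AB fragments (each of the two
#' haplotypes contributing binomially), the read starts at the enzyme-A
#' (barcoded-adapter) cut end, the sample's in-line barcode occupies the
#' first k cycles, and i.i.d. substitution errors are applied at
#' `per_base_error` across the whole read. Quality strings are constant
#' at the Phred score consistent with the error rate
#' (Q = -10 log10(e)).
#'
#' @param samples A `ddrad_samples` object (see [derive_samples()]).
#' @param enzymeA,enzymeB Enzymes; A is the barcoded-adapter cutter.
#' @param model [size_selection_model()] governing fragment recovery.
#' @param reads_per_sample Total reads per individual.
#' @param read_length Total sequenced cycles, barcode included (default
#'   36; the genomic portion is `read_length - nchar(barcode)`).
#' @param barcodes Optional barcode vector (default [make_barcodes()]).
#' @param per_base_error Per-base substitution error rate (default 0.002,
#'   a realistic short-read platform value).
#' @param seed Optional integer seed.
#' @return Object of class `ddrad_sim`: `reads`, `quals`, `ids`, the
#'   sample `sheet`, and `truth` (per-read sample/haplotype/locus/error
#'   count plus the locus table and planted variants).
#' @export
simulate_library <- function(samples, enzymeA = "EcoRI", enzymeB = "MspI",
                             model = size_selection_model(300, 25),
                             reads_per_sample = 20000L, read_length = 36L,
                             barcodes = NULL, per_base_error = 0.002,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_samples <- samples$n_samples
  if (is.null(barcodes)) barcodes <- make_barcodes(n_samples)
  if (length(barcodes) < n_samples) stop("need one barcode per sample")
  k <- nchar(barcodes[1])
  insert_len <- read_length - k
  if (insert_len < 1L) stop("read_length must exceed the barcode length")

  # digest each distinct haplotype sequence once
  hap_seqs <- unique(unlist(samples$haplotypes))
  frag_tabs <- lapply(hap_seqs, oriented_ab_fragments, enzymeA = enzymeA,
                      enzymeB = enzymeB)
  names(frag_tabs) <- hap_seqs
  if (all(vapply(frag_tabs, is.null, logical(1))))
    stop("no AB fragments recovered: digest/size-selection mismatch")

  reads <- character(0); truth_sample <- character(0)
  truth_hap <- integer(0); truth_locus <- character(0)
  for (i in seq_len(n_samples)) {
    n_h1 <- stats::rbinom(1, reads_per_sample, 0.5)
    for (h in 1:2) {
      nh <- if (h == 1L) n_h1 else reads_per_sample - n_h1
      if (nh == 0L) next
      ab <- frag_tabs[[samples$haplotypes[[i]][h]]]
      if (is.null(ab)) stop("haplotype with no AB fragments in window")
      w <- selection_weights(ab$length, model)
      cnt <- simulate_read_allocation(w, nh)
      sel <- rep(seq_len(nrow(ab)), cnt)
      reads <- c(reads, paste0(barcodes[i],
                               substr(ab$read_template[sel], 1L, insert_len)))
      truth_sample <- c(truth_sample, rep(samples$sample_id[i], nh))
      truth_hap <- c(truth_hap, rep(h, nh))
      truth_locus <- c(truth_locus, ab$locus[sel])
    }
  }
  err <- inject_errors(reads, per_base_error, read_length)
  q <- if (per_base_error > 0) round(-10 * log10(per_base_error)) else 40L
  quals <- strrep(intToUtf8(q + 33L), nchar(err$reads))
  ids <- sprintf("sim_%07d", seq_along(err$reads))
  sheet <- data.frame(flowcell = "SIMFC", lane = "1",
                      barcode = barcodes[seq_len(n_samples)], index = "",
                      sample_id = samples$sample_id,
                      stringsAsFactors = FALSE)
  loci <- unique(do.call(rbind, unname(
    lapply(frag_tabs[!vapply(frag_tabs, is.null, logical(1))],
           function(t) t[, c("locus", "length")]))))
  structure(list(reads = err$reads, quals = quals, ids = ids, sheet = sheet,
                 barcodes = stats::setNames(barcodes[seq_len(n_samples)],
                                            samples$sample_id),
                 read_length = read_length, barcode_length = k,
                 truth = list(sample = truth_sample, hap = truth_hap,
                              locus = truth_locus, n_errors = err$n_errors,
                              loci = loci, variants = samples$variants,
                              samples = samples)),
            class = "ddrad_sim")
}

#' @export
print.ddrad_sim <- function(x, ...) {
  cat(sprintf("<ddrad_sim> %d reads x %d bp, %d samples, %d true loci\n",
              length(x$reads), x$read_length, nrow(x$sheet),
              length(unique(x$truth$locus))))
  invisible(x)
}

#' Write a simulated library to FASTQ + sample sheet
#'
#' @param sim A `ddrad_sim`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulated_library <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fq <- file.path(dir, "lane1.fastq")
  write_fastq(sim$reads, sim$quals, sim$ids, fq)
  sh <- file.path(dir, "samples.tsv")
  utils::write.table(sim$sheet, sh, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fastq = fq, sheet = sh))
}

#' Score pipeline outputs against simulation truth
#'
#' Matches every unique sequence back to the true locus its reads came
#' from (majority vote over contributing reads) and computes:
#' `demux_accuracy` (reads routed to their true sample),
#' `co_clustering` (reads whose cluster's majority locus is their own
#' true locus), `read_incorporation` (reads landing in retained
#' clusters, of the reads that entered clustering), `locus_recovery`
#' (true loci with >= `c` reads that end up as a retained cluster), and
#' planted-SNP `snp_recall`/`snp_precision` over well-covered loci.
#'
#' @param result A `ddrad_result` from [ddrad_denovo()].
#' @param demux The `demux_result` the pipeline consumed.
#' @param sim The `ddrad_sim` truth object.
#' @param c Coverage threshold for locus recovery (default 7).
#' @return Named list of metrics (fractions in `[0, 1]`).
#' @export
evaluate_recovery <- function(result, demux, sim, c = 7) {
  k <- sim$barcode_length
  trimmed <- substr(sim$reads, k + 1L, nchar(sim$reads))
  # majority true locus per distinct trimmed read string
  locus_tab <- vapply(split(sim$truth$locus, trimmed),
                      function(l) names(which.max(table(l))), character(1))
  uniq <- result$uniq
  uniq_locus <- unname(locus_tab[uniq$sequence])

  demux_accuracy <- mean(demux$sample_id == sim$truth$sample, na.rm = FALSE)
  demux_accuracy <- sum(!is.na(demux$sample_id) &
                          demux$sample_id == sim$truth$sample) /
    length(sim$reads)

  memb <- result$clusters$membership
  w <- uniq$total
  cl_majority <- vapply(split(seq_along(memb), memb), function(idx) {
    tt <- tapply(w[idx], uniq_locus[idx], sum)
    names(which.max(tt))
  }, character(1))
  co_clustering <- sum(w[uniq_locus == cl_majority[as.character(memb)]],
                       na.rm = TRUE) / sum(w)

  verdicts <- vapply(result$sets, `[[`, character(1), "verdict")
  retained_cl <- which(verdicts == "retained")
  in_retained <- memb %in% retained_cl
  read_incorporation <- sum(w[in_retained]) / sum(w)

  true_counts <- table(sim$truth$locus)
  covered <- names(true_counts)[true_counts >= c]
  recovered <- unique(cl_majority[as.character(retained_cl)])
  locus_recovery <- mean(covered %in% recovered)

  snp <- evaluate_snps(result, sim, cl_majority, retained_cl, c = c)

  list(demux_accuracy = demux_accuracy,
       co_clustering = co_clustering,
       read_incorporation = read_incorporation,
       locus_recovery = locus_recovery,
       snp_recall = snp$recall, snp_precision = snp$precision)
}

# planted-variant discovery: compare the two top members of each retained
# cluster; mismatch columns are discovered SNPs in pseudo-read coordinates
evaluate_snps <- function(result, sim, cl_majority, retained_cl, c = 7) {
  uniq <- result$uniq
  insert_len <- sim$read_length - sim$barcode_length
  vpos <- sim$truth$variants$pos
  # planted variant -> (locus, offset within the sequenced window)
  planted <- list()
  for (li in seq_len(nrow(sim$truth$loci))) {
    key <- sim$truth$loci$locus[li]
    strand <- substr(key, 1, 1)
    anchor <- as.numeric(substr(key, 2, nchar(key)))
    if (strand == "F") {
      hit <- which(vpos > anchor & vpos <= anchor + insert_len)
      off <- vpos[hit] - anchor
    } else {
      hit <- which(vpos <= anchor & vpos > anchor - insert_len)
      off <- anchor - vpos[hit] + 1L
    }
    if (length(hit))
      planted[[key]] <- unique(c(planted[[key]], off))
  }
  found <- 0L; total_planted <- 0L; called <- 0L; true_called <- 0L
  for (ci in retained_cl) {
    set <- result$sets[[ci]]
    locus <- cl_majority[[as.character(ci)]]
    members <- set$members
    if (length(members) < 2L) next
    ord <- order(-uniq$total[members])
    top2 <- members[ord[1:2]]
    # a genuine minor haplotype is a substantial fraction of the major one;
    # recurrent error variants are not (each arises at ~e/3 per read)
    if (uniq$total[top2[2]] < max(c, 0.1 * uniq$total[top2[1]]))
      next
    a <- uniq$sequence[top2[1]]; b <- uniq$sequence[top2[2]]
    if (nchar(a) != nchar(b)) next
    ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
    mism <- which(ac != bc)
    truthpos <- planted[[locus]]
    if (is.null(truthpos)) truthpos <- integer(0)
    total_planted <- total_planted + length(truthpos)
    found <- found + sum(truthpos %in% mism)
    called <- called + length(mism)
    true_called <- true_called + sum(mism %in% truthpos)
  }
  list(recall = if (total_planted > 0) found / total_planted else NA_real_,
       precision = if (called > 0) true_called / called else NA_real_)
}
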