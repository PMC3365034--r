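# phred+33 quality string -> integer matrix (reads x positions), equal lengths
qual_to_matrix <- function(quals, L) {
  matrix(utf8ToInt(paste(quals, collapse = "")) - 33L,
         ncol = L, byrow = TRUE)
}

#' Collapse identical reads into unique-sequence records
#'
#' Collapses all character-identical sequences (post barcode trim) within
#' a lane into one record each, retaining the number of observations per
#' sample, the arithmetic mean per-base Phred quality over all
#' observations, and optionally the associated unique mate sequences with
#' counts. No quality or singleton filtering is applied: error-containing
#' reads are kept because most errors fall at non-polymorphic sites and
#' the reads remain informative for clustering.
#'
#' Reads of different lengths are grouped by length and collapsed within
#' each group. The result is ordered lexicographically by sequence, so it
#' is invariant to the input read order.
#'
#' @param reads Character vector of read sequences, or a `demux_result`
#'   (assigned reads are taken together with their sample ids).
#' @param quals Phred+33 quality strings, same lengths as `reads`.
#' @param samples Sample id per read.
#' @param mates Optional mate sequence per read (paired-end).
#' @return Object of class `uniq_set` with elements `sequence` (character
#'   vector), `counts` (sequence x sample integer matrix), `total`
#'   (row sums), `qual` (list of per-position mean Phred vectors), and
#'   optionally `pairs` (list of named mate-count vectors).
#' @export
collapse_reads <- function(reads, quals = NULL, samples = NULL, mates = NULL) {
  if (inherits(reads, "demux_result")) {
    keep <- reads$reason == "assigned"
    samples <- reads$sample_id[keep]
    quals <- reads$quals[keep]
    mates <- if (!is.null(reads$reads2)) reads$reads2[keep] else NULL
    reads <- reads$reads[keep]
  }
  if (length(reads) == 0L) stop("no reads to collapse")
  reads <- toupper(reads)
  if (is.null(samples)) samples <- rep("sample1", length(reads))
  if (is.null(quals)) quals <- strrep("I", nchar(reads))
  if (any(nchar(quals) != nchar(reads)))
    stop("malformed FASTQ: quality string length differs from sequence length")

  sample_levels <- sort(unique(samples))
  by_len <- split(seq_along(reads), nchar(reads))
  parts <- lapply(by_len, function(idx) {
    L <- nchar(reads[idx[1]])
    f <- factor(reads[idx])
    counts <- table(f, factor(samples[idx], levels = sample_levels))
    counts <- matrix(as.integer(counts), nrow = nlevels(f),
                     dimnames = list(levels(f), sample_levels))
    qsum <- rowsum(qual_to_matrix(quals[idx], L), f)
    qmean <- qsum / rowSums(counts)
    pairs <- NULL
    if (!is.null(mates)) {
      pairs <- lapply(split(mates[idx], f), function(m) {
        tb <- table(m)
        stats::setNames(as.integer(tb), names(tb))
      })
    }
    list(sequence = levels(f), counts = counts,
         qual = lapply(seq_len(nrow(qmean)), function(i) unname(qmean[i, ])),
         pairs = pairs)
  })
  parts <- unname(parts)
  sequence <- unlist(lapply(parts, `[[`, "sequence"), use.names = FALSE)
  counts <- do.call(rbind, lapply(parts, `[[`, "counts"))
  qual <- do.call(c, lapply(parts, function(p) unname(p$qual)))
  pairs <- if (!is.null(mates))
    do.call(c, lapply(parts, function(p) unname(p$pairs))) else NULL
  ord <- order(sequence)
  structure(list(sequence = sequence[ord],
                 counts = counts[ord, , drop = FALSE],
                 total = as.integer(rowSums(counts[ord, , drop = FALSE])),
                 qual = qual[ord],
                 pairs = if (!is.null(pairs)) pairs[ord] else NULL),
            class = "uniq_set")
}

#' @export
print.uniq_set <- function(x, ...) {
  cat(sprintf("<uniq_set> %d unique sequences, %d reads, %d samples\n",
              length(x$sequence), sum(x$total), ncol(x$counts)))
  invisible(x)
}

#' Merge unique-sequence sets from multiple lanes
#'
#' Unifies two collapsed sets: counts for sequences present in both are
#' summed per sample, and mean qualities are recombined as count-weighted
#' means. Both sets must use the same trimming conventions; identical
#' sequences with differing lengths indicate corrupt input.
#'
#' @param a,b `uniq_set` objects.
#' @return Merged `uniq_set`.
#' @export
merge_collapsed <- function(a, b) {
  stopifnot(inherits(a, "uniq_set"), inherits(b, "uniq_set"))
  samples <- sort(unique(c(colnames(a$counts), colnames(b$counts))))
  seqs <- sort(unique(c(a$sequence, b$sequence)))
  n <- length(seqs)
  counts <- matrix(0L, n, length(samples), dimnames = list(seqs, samples))
  qualsum <- vector("list", n)
  for (set in list(a, b)) {
    ia <- match(set$sequence, seqs)
    cols <- match(colnames(set$counts), samples)
    idx <- cbind(rep(ia, length(cols)), rep(cols, each = length(ia)))
    counts[idx] <- counts[idx] + as.vector(set$counts)
    for (r in seq_along(ia)) {
      i <- ia[r]
      contrib <- set$qual[[r]] * set$total[r]
      if (is.null(qualsum[[i]])) qualsum[[i]] <- contrib
      else {
        if (length(qualsum[[i]]) != length(contrib))
          stop("data-integrity error: identical sequences with different quality lengths")
        qualsum[[i]] <- qualsum[[i]] + contrib
      }
    }
  }
  total <- as.integer(rowSums(counts))
  structure(list(sequence = seqs, counts = counts, total = total,
                 qual = lapply(seq_len(n), function(i) qualsum[[i]] / total[i]),
                 pairs = NULL),
            class = "uniq_set")
}

#' Write / read a unique-sequence table
#'
#' TSV serialisation of a `uniq_set`: sequence, total count, per-sample
#' counts (`sample:count` pairs, `;`-joined), and per-position mean
#' qualities (comma-joined, 2 decimals).
#'
#' @param uniq A `uniq_set`.
#' @param path File path.
#' @return `read_uniq_table` returns a `uniq_set`.
#' @export
write_uniq_table <- function(uniq, path) {
  counts_str <- apply(uniq$counts, 1, function(cc) {
    nz <- cc > 0
    paste(paste0(colnames(uniq$counts)[nz], ":", cc[nz]), collapse = ";")
  })
  qual_str <- vapply(uniq$qual, function(q) paste(sprintf("%.2f", q), collapse = ","),
                     character(1))
  utils::write.table(
    data.frame(sequence = uniq$sequence, total = uniq$total,
               counts = counts_str, mean_quality = qual_str),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_uniq_table
#' @export
read_uniq_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  pairs <- strsplit(tab$counts, ";", fixed = TRUE)
  samples <- sort(unique(sub(":.*$", "", unlist(pairs))))
  counts <- matrix(0L, nrow(tab), length(samples),
                   dimnames = list(tab$sequence, samples))
  for (i in seq_len(nrow(tab))) {
    kv <- strsplit(pairs[[i]], ":", fixed = TRUE)
    for (p in kv) counts[i, p[1]] <- as.integer(p[2])
  }
  structure(list(sequence = tab$sequence, counts = counts,
                 total = as.integer(rowSums(counts)),
                 qual = lapply(strsplit(tab$mean_quality, ","), as.numeric),
                 pairs = NULL),
            class = "uniq_set")
}
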