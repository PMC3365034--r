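#' Generate an in-line barcode set with guaranteed minimum distance 2
#'
#' Deterministic synthetic barcode design using a parity-check code: every
#' barcode is a (k-1)-mer over {A,C,G,T} followed by a checksum base (sum
#' of base indices mod 4), so any two barcodes differ at a minimum of 2
#' positions. This satisfies the design rule that makes single-mismatch
#' barcode correction safe.
#'
#' @param n Number of barcodes (at most `4^(k-1)`).
#' @param k Barcode length in bases (default 5).
#' @return Character vector of `n` distinct barcodes.
#' @examples
#' validate_barcode_set(make_barcodes(48))
#' @export
make_barcodes <- function(n, k = 5L) {
  if (n > 4^(k - 1)) stop("at most 4^(k-1) barcodes of length k are available")
  bases <- c("A", "C", "G", "T")
  digits <- as.matrix(expand.grid(rep(list(0:3), k - 1L),
                                  KEEP.OUT.ATTRS = FALSE))[seq_len(n), , drop = FALSE]
  check <- rowSums(digits) %% 4L
  apply(cbind(digits, check), 1, function(d) paste(bases[d + 1L], collapse = ""))
}

# pairwise Hamming distance matrix for equal-length strings
hamming_matrix <- function(x) {
  k <- unique(nchar(x))
  if (length(k) != 1L) stop("barcodes must all have the same length")
  chars <- matrix(unlist(strsplit(x, "")), ncol = k, byrow = TRUE)
  n <- length(x)
  d <- matrix(0L, n, n)
  for (p in seq_len(k)) d <- d + outer(chars[, p], chars[, p], "!=")
  d
}

#' Validate an in-line barcode set
#'
#' Computes the minimum pairwise Hamming distance of a barcode set. A
#' minimum distance of at least 2 is required for safe single-mismatch
#' assignment: with distance >= 2, a one-base sequencing error can never
#' convert one barcode into a read uniquely matching a different barcode.
#'
#' @param barcodes Character vector of >= 2 equal-length barcodes.
#' @param warn Emit a warning when the minimum distance is < 2.
#' @return Minimum pairwise Hamming distance (integer).
#' @export
validate_barcode_set <- function(barcodes, warn = TRUE) {
  if (length(barcodes) < 2L) stop("need at least two barcodes")
  if (anyDuplicated(barcodes)) stop("barcodes must be distinct")
  d <- hamming_matrix(toupper(barcodes))
  mind <- min(d[upper.tri(d)])
  if (warn && mind < 2L)
    warning("minimum pairwise barcode distance is ", mind,
            ": single-mismatch correction is unsafe")
  as.integer(mind)
}

# mismatch counts of each read prefix against each barcode:
# returns n_reads x n_barcodes integer matrix
barcode_mismatches <- function(reads, barcodes) {
  k <- nchar(barcodes[1])
  pre <- substr(reads, 1L, k)
  chars <- matrix(unlist(strsplit(pre, "")), ncol = k, byrow = TRUE)
  bc <- matrix(unlist(strsplit(barcodes, "")), ncol = k, byrow = TRUE)
  mm <- matrix(0L, nrow = length(reads), ncol = length(barcodes))
  for (p in seq_len(k))
    mm <- mm + outer(chars[, p], bc[, p], "!=")
  mm
}

#' Assign one read to a sample by its in-line barcode
#'
#' Compares the first k bases of the read against every barcode in the
#' lane's set and assigns the read iff exactly one barcode lies within
#' `max_mismatch` (default 1). Reads matching none are `no_match`; reads
#' within range of two or more barcodes are `ambiguous`.
#'
#' @param read Read sequence (character scalar).
#' @param barcodes Named character vector: names are sample ids, values
#'   barcodes (equal length k).
#' @param max_mismatch Maximum Hamming mismatches allowed (default 1).
#' @return List with `sample_id` (NA when unassigned), `barcode`, and
#'   `reason` in `assigned`/`no_match`/`ambiguous`.
#' @export
assign_read <- function(read, barcodes, max_mismatch = 1L) {
  k <- nchar(barcodes[[1]])
  if (nchar(read) < k)
    return(list(sample_id = NA_character_, barcode = NA_character_,
                reason = "no_match"))
  mm <- barcode_mismatches(read, as.character(barcodes))[1, ]
  hit <- which(mm <= max_mismatch)
  if (length(hit) == 1L)
    list(sample_id = names(barcodes)[hit], barcode = barcodes[[hit]],
         reason = "assigned")
  else
    list(sample_id = NA_character_, barcode = NA_character_,
         reason = if (length(hit) == 0L) "no_match" else "ambiguous")
}

# vectorized assignment; returns data.frame(sample_id, reason)
assign_reads <- function(reads, barcodes, max_mismatch = 1L) {
  k <- nchar(barcodes[[1]])
  n <- length(reads)
  sample_id <- rep(NA_character_, n)
  reason <- rep("no_match", n)
  long <- nchar(reads) >= k
  if (any(long)) {
    mm <- barcode_mismatches(reads[long], as.character(barcodes))
    nhit <- rowSums(mm <= max_mismatch)
    best <- max.col(-mm, ties.method = "first")
    ok <- nhit == 1L
    idx <- which(long)
    sample_id[idx[ok]] <- names(barcodes)[best[ok]]
    reason[idx[ok]] <- "assigned"
    reason[idx[nhit > 1L]] <- "ambiguous"
  }
  data.frame(sample_id = sample_id, reason = reason, stringsAsFactors = FALSE)
}

#' Read a demultiplexing sample sheet
#'
#' The sample sheet replaces a LIMS: a TSV/CSV table with columns
#' `flowcell`, `lane`, `barcode`, optional `index`, and `sample_id`, one
#' row per sample. Within a lane (and index) all barcodes must share one
#' length and each (lane, barcode, index) combination must be unique.
#'
#' @param path TSV (default) or CSV file; a data.frame is passed through
#'   validation unchanged.
#' @return Validated sample-sheet data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- if (is.data.frame(path)) path
  else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    utils::read.table(path, sep = sep, header = TRUE,
                      stringsAsFactors = FALSE,
                      colClasses = "character")
  }
  need <- c("flowcell", "lane", "barcode", "sample_id")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (!"index" %in% names(sheet)) sheet$index <- ""
  sheet$index[is.na(sheet$index)] <- ""
  sheet$barcode <- toupper(sheet$barcode)
  key <- paste(sheet$lane, sheet$barcode, sheet$index)
  if (anyDuplicated(key))
    stop("(lane, barcode, index) combinations must be unique in the sheet")
  for (grp in split(sheet, paste(sheet$lane, sheet$index))) {
    if (length(unique(nchar(grp$barcode))) != 1L)
      stop("all barcodes within one lane/index must share the same length")
  }
  sheet
}

#' Demultiplex a FASTQ lane by in-line barcode
#'
#' Routes every read of a lane to exactly one sample (or the unassigned
#' bin) by matching its first k bases against the lane's barcode set with
#' at most one mismatch. The barcode bases are trimmed from the emitted
#' reads (and qualities), so downstream unique-sequence identity excludes
#' barcode bases. Paired mates follow the assignment of read 1. Index
#' matching is exact: the `index` argument selects the sheet rows for an
#' index-binned file.
#'
#' @param fastq Path to a FASTQ file (gzip ok) or a list with elements
#'   `reads` and `quals` (character vectors) for in-memory input.
#' @param sheet Sample sheet (path or data.frame; see
#'   [read_sample_sheet()]).
#' @param lane Lane to demultiplex (matched against the sheet).
#' @param index Multiplex index of this file, when the sheet uses indices.
#' @param fastq2 Optional mate FASTQ (path or list), kept synchronised.
#' @param max_mismatch Maximum barcode mismatches (default 1).
#' @param output_dir When given, per-sample FASTQ files plus an
#'   `unassigned.fastq` sidecar (reason codes in the headers) are written
#'   there.
#' @return Object of class `demux_result`: per-read `sample_id` and
#'   `reason`, trimmed `reads`/`quals` (and mates), per-sample `counts`,
#'   and the overall `assignment_rate`.
#' @export
demultiplex_fastq <- function(fastq, sheet, lane, index = NULL,
                              fastq2 = NULL, max_mismatch = 1L,
                              output_dir = NULL) {
  sheet <- read_sample_sheet(sheet)
  rows <- sheet[sheet$lane == as.character(lane), , drop = FALSE]
  idx_vals <- unique(rows$index)
  if (is.null(index)) {
    if (length(idx_vals) > 1L || any(nzchar(idx_vals)))
      stop("sheet uses multiplex indices for this lane; supply `index`")
  } else {
    rows <- rows[rows$index == index, , drop = FALSE]
  }
  if (nrow(rows) == 0L) stop("no sample-sheet rows for this lane/index")
  barcodes <- stats::setNames(rows$barcode, rows$sample_id)
  if (length(barcodes) >= 2L) validate_barcode_set(barcodes)

  r1 <- read_fastq_input(fastq)
  r2 <- if (!is.null(fastq2)) read_fastq_input(fastq2) else NULL
  if (!is.null(r2) && length(r2$reads) != length(r1$reads))
    stop("mate FASTQ has a different read count")

  asg <- assign_reads(r1$reads, barcodes, max_mismatch = max_mismatch)
  k <- nchar(barcodes[[1]])
  trimmed <- ifelse(asg$reason == "assigned",
                    substr(r1$reads, k + 1L, nchar(r1$reads)), r1$reads)
  trimmedq <- ifelse(asg$reason == "assigned",
                     substr(r1$quals, k + 1L, nchar(r1$quals)), r1$quals)
  counts <- table(factor(asg$sample_id, levels = rows$sample_id))
  res <- structure(list(
    sample_id = asg$sample_id, reason = asg$reason,
    reads = trimmed, quals = trimmedq,
    reads2 = r2$reads, quals2 = r2$quals,
    ids = r1$ids,
    counts = counts,
    n_total = length(r1$reads),
    assignment_rate = mean(asg$reason == "assigned")
  ), class = "demux_result")
  if (!is.null(output_dir)) write_demux_fastq(res, output_dir)
  res
}

#' @export
print.demux_result <- function(x, ...) {
  cat(sprintf("<demux_result> %d reads, %.1f%% assigned to %d samples\n",
              x$n_total, 100 * x$assignment_rate, length(x$counts)))
  invisible(x)
}

# accept a path or list(reads=, quals=, ids=)
read_fastq_input <- function(x) {
  if (is.list(x) && !is.null(x$reads)) {
    quals <- x$quals
    if (is.null(quals)) quals <- strrep("I", nchar(x$reads))
    ids <- x$ids
    if (is.null(ids)) ids <- paste0("read", seq_along(x$reads))
    return(list(reads = toupper(as.character(x$reads)),
                quals = as.character(quals), ids = ids))
  }
  ss <- Biostrings::readDNAStringSet(x, format = "fastq", with.qualities = TRUE)
  list(reads = as.character(ss),
       quals = as.character(S4Vectors::mcols(ss)$qualities),
       ids = names(ss))
}

write_demux_fastq <- function(res, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  grp <- ifelse(is.na(res$sample_id), "unassigned", res$sample_id)
  for (s in unique(grp)) {
    sel <- grp == s
    ids <- res$ids[sel]
    if (s == "unassigned") ids <- paste(ids, res$reason[sel])
    write_fastq(res$reads[sel], res$quals[sel], ids,
                file.path(output_dir, paste0(s, ".fastq")))
  }
  invisible(output_dir)
}

# minimal FASTQ emitter over Biostrings
write_fastq <- function(reads, quals, ids, path) {
  dna <- Biostrings::DNAStringSet(reads)
  names(dna) <- ids
  q <- Biostrings::BStringSet(quals)
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = q)
  invisible(path)
}
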