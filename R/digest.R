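#' Find restriction-enzyme cut positions in a sequence
#'
#' Scans both strands for the enzyme's recognition site and returns the
#' sorted, de-duplicated top-strand cut positions (0-based: the cut falls
#' between positions `p - 1` and `p`). A site found on the reverse strand
#' cuts the top strand at `site_start + site_length - cut_offset`; for
#' palindromic enzymes the two strands give identical cut sets. Recognition
#' sites never match across N or other ambiguity characters.
#'
#' @param sequence Character scalar or [Biostrings::DNAString] over
#'   A/C/G/T/N.
#' @param enzyme Enzyme name (see [ddrad_enzymes()]) or a
#'   [restriction_enzyme()] object.
#' @return Integer vector of strictly increasing 0-based cut positions.
#' @examples
#' find_cut_sites("AAGAATTCAA", "EcoRI")  # cut G^AATTC -> 3
#' @export
find_cut_sites <- function(sequence, enzyme) {
  enzyme <- get_enzyme(enzyme)
  if (inherits(sequence, "DNAString")) sequence <- as.character(sequence)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) return(integer(0))
  subject <- Biostrings::DNAString(sequence)
  site <- enzyme$recognition
  len <- nchar(site)
  # fixed = TRUE: N in the subject never matches a concrete base
  fwd <- Biostrings::start(Biostrings::matchPattern(site, subject, fixed = TRUE))
  cuts <- fwd - 1L + enzyme$cut_offset
  rcsite <- revcomp(site)
  if (rcsite != site) {
    rev <- Biostrings::start(Biostrings::matchPattern(rcsite, subject, fixed = TRUE))
    cuts <- c(cuts, rev - 1L + (len - enzyme$cut_offset))
  }
  sort(unique(as.integer(cuts)))
}

#' In-silico double restriction digest of one sequence
#'
#' Complete-digest model: the merged cut positions of both enzymes
#' partition the sequence into fragments that tile it exactly. Each
#' fragment is labelled with its flanking enzymes and classified as
#' `AB` (one end from each enzyme), `AA`, `BB`, or `end` (terminal piece
#' bounded by a chromosome end). Only AB fragments carry both adapter
#' types and enter a ddRAD library.
#'
#' @param sequence Character scalar or [Biostrings::DNAString].
#' @param enzymeA,enzymeB Distinct enzymes (names or objects). Enzyme A is
#'   the rare/barcoded-adapter cutter by convention.
#' @param seq_id Identifier recorded in the fragment table.
#' @return A data.frame with columns `seq_id`, `start`, `end` (0-based
#'   half-open), `length`, `left_enzyme`, `right_enzyme`, `frag_class`.
#' @examples
#' double_digest("AAGAATTCAAAACCGGAAAA", "EcoRI", "MspI")
#' @export
double_digest <- function(sequence, enzymeA, enzymeB, seq_id = "seq") {
  enzymeA <- get_enzyme(enzymeA)
  enzymeB <- get_enzyme(enzymeB)
  if (identical(enzymeA$name, enzymeB$name))
    stop("double_digest requires two distinct enzymes")
  if (inherits(sequence, "DNAString")) sequence <- as.character(sequence)
  slen <- nchar(sequence)
  cutsA <- find_cut_sites(sequence, enzymeA)
  cutsB <- find_cut_sites(sequence, enzymeB)
  # interior cuts only: a cut at 0 or slen leaves no terminal fragment
  cuts <- rbind(
    data.frame(pos = cutsA, enz = rep(enzymeA$name, length(cutsA))),
    data.frame(pos = cutsB, enz = rep(enzymeB$name, length(cutsB)))
  )
  cuts <- cuts[cuts$pos > 0L & cuts$pos < slen, , drop = FALSE]
  cuts <- cuts[order(cuts$pos), , drop = FALSE]
  # a palindrome overlap could place both enzymes at one position; keep first
  cuts <- cuts[!duplicated(cuts$pos), , drop = FALSE]
  bounds <- c(0L, cuts$pos, slen)
  left <- c("chromosome-end", cuts$enz)
  right <- c(cuts$enz, "chromosome-end")
  cls <- ifelse(
    left == "chromosome-end" | right == "chromosome-end", "end",
    ifelse(left == right,
           ifelse(left == enzymeA$name, "AA", "BB"),
           "AB")
  )
  data.frame(
    seq_id = seq_id,
    start = bounds[-length(bounds)],
    end = bounds[-1],
    length = diff(bounds),
    left_enzyme = left,
    right_enzyme = right,
    frag_class = cls,
    stringsAsFactors = FALSE
  )
}

#' Digest every record of a genome
#'
#' Applies [double_digest()] to each sequence of a genome given as a FASTA
#' file (gzip allowed) or a [Biostrings::DNAStringSet], concatenating the
#' per-sequence fragment tables.
#'
#' @param genome Path to a FASTA file or a `DNAStringSet`.
#' @inheritParams double_digest
#' @return Combined fragment data.frame (see [double_digest()]).
#' @export
digest_genome <- function(genome, enzymeA, enzymeB) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(genome))
    genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome)))
    names(genome) <- paste0("seq", seq_along(genome))
  tabs <- lapply(seq_along(genome), function(i) {
    double_digest(as.character(genome[[i]]), enzymeA, enzymeB,
                  seq_id = sub("\\s.*$", "", names(genome)[i]))
  })
  do.call(rbind, tabs)
}

#' Select AB fragments inside a size window
#'
#' Returns the AB-class fragments whose length lies in the closed interval
#' `[lo, hi]` — the fragment set a precise size selection would retain.
#'
#' @param fragments Fragment data.frame from [double_digest()].
#' @param lo,hi Window bounds in bp, inclusive.
#' @param exclude_N Optionally drop fragments whose sequence contains N
#'   (requires a `has_N` column; default keeps them).
#' @return The selected subset of `fragments`; its `nrow` is the count.
#' @export
ab_fragments_in_window <- function(fragments, lo, hi, exclude_N = FALSE) {
  if (lo > hi) stop("window bounds must satisfy lo <= hi")
  keep <- fragments$frag_class == "AB" &
    fragments$length >= lo & fragments$length <= hi
  if (exclude_N && !is.null(fragments$has_N)) keep <- keep & !fragments$has_N
  fragments[keep, , drop = FALSE]
}

#' Fragment length histogram
#'
#' Histogram of fragment lengths at a fixed bin width, by default counting
#' AB fragments only (the class entering the library). Bins are
#' `[edge, edge + bin_width)`.
#'
#' @param fragments Fragment data.frame.
#' @param bin_width Bin width in bp.
#' @param frag_class Class to include (`"AB"` by default, `NULL` for all).
#' @return List with `breaks` (bin left edges, length n+1 including the
#'   right edge of the last bin) and `counts`.
#' @export
fragment_length_histogram <- function(fragments, bin_width = 50,
                                      frag_class = "AB") {
  lens <- fragments$length
  if (!is.null(frag_class)) lens <- lens[fragments$frag_class %in% frag_class]
  if (length(lens) == 0L)
    return(list(breaks = numeric(0), counts = integer(0)))
  lo <- floor(min(lens) / bin_width) * bin_width
  hi <- (floor(max(lens) / bin_width) + 1) * bin_width
  breaks <- seq(lo, hi, by = bin_width)
  counts <- as.integer(table(cut(lens, breaks = breaks, right = FALSE,
                                 include.lowest = FALSE)))
  list(breaks = breaks, counts = counts)
}

#' Write / read a fragment table
#'
#' Plain TSV serialisation of the fragment table produced by
#' [double_digest()] / [digest_genome()].
#'
#' @param fragments Fragment data.frame.
#' @param path File path.
#' @return `read_fragment_table` returns the fragment data.frame.
#' @export
write_fragment_table <- function(fragments, path) {
  utils::write.table(fragments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragment_table
#' @export
read_fragment_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
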