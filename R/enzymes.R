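#' Define a restriction enzyme
#'
#' A restriction enzyme is described by its recognition sequence and the
#' offset of the top-strand cut point from the 5' start of the recognition
#' site. Offsets follow REBASE conventions, e.g. EcoRI cuts G^AATTC
#' (offset 1) and NlaIII cuts CATG^ (offset 4).
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence over A/C/G/T, 4-8 bp.
#' @param cut_offset Integer offset of the top-strand cut from the 5' start
#'   of the recognition site; must lie in `[0, nchar(recognition)]`.
#' @return An object of class `restriction_enzyme`.
#' @examples
#' restriction_enzyme("EcoRI", "GAATTC", 1)
#' @export
restriction_enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(as.character(recognition))
  if (!nzchar(recognition) || grepl("[^ACGT]", recognition))
    stop("recognition sequence must be a non-empty string over A/C/G/T")
  if (nchar(recognition) < 4L || nchar(recognition) > 8L)
    stop("recognition sequence must be 4-8 bp")
  cut_offset <- as.integer(cut_offset)
  if (is.na(cut_offset) || cut_offset < 0L || cut_offset > nchar(recognition))
    stop("cut_offset must lie within the recognition site")
  structure(
    list(name = as.character(name), recognition = recognition,
         cut_offset = cut_offset),
    class = "restriction_enzyme"
  )
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  site <- paste0(substr(x$recognition, 1, x$cut_offset), "^",
                 substr(x$recognition, x$cut_offset + 1, nchar(x$recognition)))
  cat(sprintf("<restriction_enzyme> %s  %s\n", x$name, site))
  invisible(x)
}

#' Built-in restriction enzymes
#'
#' The enzyme set commonly used for ddRADseq design: frequent four-cutters
#' (MspI, NlaIII, MluCI), the six-cutters EcoRI and SphI, and the
#' eight-cutter SbfI. Cut offsets follow REBASE.
#'
#' @return Named list of [restriction_enzyme()] objects.
#' @examples
#' names(ddrad_enzymes())
#' @export
ddrad_enzymes <- function() {
  list(
    EcoRI = restriction_enzyme("EcoRI", "GAATTC", 1L),
    MspI  = restriction_enzyme("MspI",  "CCGG",   1L),
    NlaIII = restriction_enzyme("NlaIII", "CATG", 4L),
    MluCI = restriction_enzyme("MluCI", "AATT",   0L),
    SbfI  = restriction_enzyme("SbfI",  "CCTGCAGG", 6L),
    SphI  = restriction_enzyme("SphI",  "GCATGC", 5L)
  )
}

# Resolve an enzyme given by name or as a restriction_enzyme object.
get_enzyme <- function(x) {
  if (inherits(x, "restriction_enzyme")) return(x)
  if (is.character(x) && length(x) == 1L) {
    enz <- ddrad_enzymes()[[x]]
    if (!is.null(enz)) return(enz)
    stop("unknown enzyme '", x, "'; supply a restriction_enzyme object")
  }
  stop("enzyme must be a name or a restriction_enzyme object")
}

# reverse complement for plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_palindromic <- function(enzyme) {
  enzyme$recognition == revcomp(enzyme$recognition)
}
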