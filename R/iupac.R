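# IUPAC nucleotide codes as 4-bit masks (A=1, C=2, G=4, T=8).
# Two codes are compatible iff their base sets intersect, i.e. the
# bitwise AND of their masks is non-zero. The gap character has mask 0
# and therefore matches nothing, including N.

IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L,
  K = 12L, M = 3L, B = 14L, D = 13L,
  H = 11L, V = 7L, N = 15L, `-` = 0L
)

# reverse lookup: mask -> minimal IUPAC code (index mask+1; mask 0 = gap)
BITS_CODE <- local({
  out <- character(16L)
  out[1L] <- "-"
  for (code in names(IUPAC_BITS)) {
    m <- IUPAC_BITS[[code]]
    if (m > 0L) out[m + 1L] <- code
  }
  out
})

IUPAC_ALPHABET <- names(IUPAC_BITS)

#' Normalize a DNA sequence string
#'
#' Uppercases, strips whitespace, and validates that every character is
#' an IUPAC nucleotide code or the gap character `-`. Normalization is
#' idempotent: applying it twice gives the same result as applying it
#' once.
#'
#' @param x Character vector of DNA sequences (may be lowercase, e.g.
#'   primer tables are sometimes published in lowercase).
#' @return Character vector of uppercase IUPAC DNA strings.
#' @export
#' @examples
#' normalize_seq("gatgtaaactatggctggcttatt")
normalize_seq <- function(x) {
  if (!is.character(x)) stop("`x` must be a character vector", call. = FALSE)
  out <- toupper(gsub("[[:space:]]", "", x))
  bad <- vapply(out, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    any(!ch %in% IUPAC_ALPHABET)
  }, logical(1))
  if (any(bad)) {
    offending <- out[bad][1]
    stop("sequence contains non-IUPAC characters: ",
         substr(offending, 1, 40), call. = FALSE)
  }
  out
}

# integer bitmask vector for one sequence string (assumed normalized)
seq_bits <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  unname(IUPAC_BITS[ch])
}

#' Do two IUPAC codes match?
#'
#' Two codes match iff the base sets they encode intersect. `N` matches
#' every base; the gap character `-` matches nothing (a primer cannot
#' pair with a missing template base).
#'
#' @param a,b Character vectors of single IUPAC codes (recycled).
#' @return Logical vector.
#' @export
#' @examples
#' iupac_match("R", "A")  # TRUE: R = {A,G}
#' iupac_match("R", "C")  # FALSE
#' iupac_match("N", "-")  # FALSE: gaps never match
iupac_match <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (any(!a %in% IUPAC_ALPHABET) || any(!b %in% IUPAC_ALPHABET)) {
    stop("arguments must be single IUPAC codes", call. = FALSE)
  }
  bitwAnd(unname(IUPAC_BITS[a]), unname(IUPAC_BITS[b])) > 0L
}

#' Reverse complement of an IUPAC DNA string
#'
#' Handles all ambiguity codes (R<->Y, K<->M, B<->V, D<->H; S, W, N and
#' the gap are self-complementary).
#'
#' @param x Character vector of IUPAC DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  x <- normalize_seq(x)
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# minimal IUPAC code covering a set of observed codes (union of masks)
consensus_code <- function(codes) {
  m <- Reduce(bitwOr, unname(IUPAC_BITS[codes]), accumulate = FALSE)
  BITS_CODE[m + 1L]
}

#' Round half away from zero
#'
#' Reporting rounding for rates and temperatures (63.64% -> 64%,
#' 37.43 degC -> 37 degC). Base `round()` rounds half to even, which
#' does not reproduce conventionally printed percentages.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
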