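# Per-oligo physical metrics. The melting-temperature model is the
# basic GC-fraction formula Tm = 64.9 + 41*(nGC - 16.4)/N for oligos of
# at least 14 nt, with the Wallace rule 2*(A+T) + 4*(G+C) as the
# short-oligo fallback. No nearest-neighbour thermodynamics or salt
# correction: the point of the basic formula here is to flag primers
# whose Tm sits far below the assay's annealing temperature (the
# legacy bighead-carp monitoring primer melts around 37 degC against a
# 50 degC annealing step), and that screening question does not need a
# thermodynamic model.

# count of positions whose IUPAC code is unambiguously G/C (G, C or S);
# ambiguous codes that only *may* be G/C (R, Y, K, M, N, ...) are not
# counted, giving a conservative lower Tm bound
gc_count <- function(oligo) {
  bits <- seq_bits(normalize_seq(oligo))
  if (any(bits == 0L)) stop("oligo must be gap-free", call. = FALSE)
  sum(bitwAnd(bits, 9L) == 0L)  # no A (1) or T (8) possibility left
}

#' GC content of an oligo
#'
#' Fraction of positions that are unambiguously G or C (codes G, C, S).
#'
#' @param oligo IUPAC DNA string (gap-free).
#' @return Fraction in \[0, 1\].
#' @export
gc_content <- function(oligo) {
  gc_count(oligo) / nchar(normalize_seq(oligo))
}

#' Basic melting temperature
#'
#' `Tm = 64.9 + 41 * (nGC - 16.4) / N` for an oligo of length `N` with
#' `nGC` unambiguous G/C positions. Valid for oligos of at least 14 nt;
#' use [wallace_tm()] below that.
#'
#' @param oligo IUPAC DNA string, length >= 14.
#' @return Melting temperature in degrees Celsius (not rounded; use
#'   [round_half_up()] for reporting).
#' @export
#' @examples
#' basic_tm("TAACTTAAATAAACAGATTA")  # 37.43 -> reports as 37 degC
basic_tm <- function(oligo) {
  oligo <- normalize_seq(oligo)
  n <- nchar(oligo)
  if (n == 0L) stop("oligo must be non-empty", call. = FALSE)
  if (n < 14L) {
    stop("basic_tm requires length >= 14; use wallace_tm() for shorter oligos",
         call. = FALSE)
  }
  64.9 + 41 * (gc_count(oligo) - 16.4) / n
}

#' Wallace-rule melting temperature
#'
#' `Tm = 2*(A+T) + 4*(G+C)`, the standard short-oligo (< 14 nt) rule.
#' Ambiguous codes are counted as A/T unless unambiguously G/C.
#'
#' @param oligo IUPAC DNA string.
#' @return Melting temperature in degrees Celsius.
#' @export
#' @examples
#' wallace_tm("ATGC")  # 12
wallace_tm <- function(oligo) {
  oligo <- normalize_seq(oligo)
  n <- nchar(oligo)
  if (n == 0L) stop("oligo must be non-empty", call. = FALSE)
  gc <- gc_count(oligo)
  2 * (n - gc) + 4 * gc
}

#' Melting temperature with length-based model selection
#'
#' [basic_tm()] for oligos of 14 nt or more, [wallace_tm()] otherwise.
#'
#' @param oligo IUPAC DNA string.
#' @return Melting temperature in degrees Celsius.
#' @export
oligo_tm <- function(oligo) {
  if (nchar(normalize_seq(oligo)) >= 14L) basic_tm(oligo) else wallace_tm(oligo)
}

#' Mismatch profile of an oligo against a template window
#'
#' Compares an oligo position-by-position (IUPAC-aware, no indels)
#' against an equal-length template window and reports where the two
#' disagree, with special attention to the 3' end: a mismatch at the
#' extension end strongly inhibits polymerase extension, which is
#' exploited when designing species-specific primers.
#'
#' @param oligo IUPAC DNA string (5'->3').
#' @param template_window Template text of the same length, in the
#'   oligo's reading direction.
#' @param window Size of the 3'-terminal window over which mismatches
#'   are counted separately (default 5 bases).
#' @return A list of class `mismatch_profile`: `oligo_len`,
#'   `total_mismatches`, `positions` (0-based offsets from the oligo 5'
#'   end), `three_prime_terminal` (mismatch at the final base) and
#'   `three_prime_window` (mismatch count within the last `window`
#'   bases).
#' @export
mismatch_profile <- function(oligo, template_window, window = 5L) {
  oligo <- normalize_seq(oligo)
  template_window <- normalize_seq(template_window)
  n <- nchar(oligo)
  if (n != nchar(template_window)) {
    stop("oligo and template window must have equal length", call. = FALSE)
  }
  ob <- seq_bits(oligo)
  tb <- seq_bits(template_window)
  mism <- bitwAnd(ob, tb) == 0L
  pos <- which(mism) - 1L
  structure(
    list(
      oligo_len = n,
      total_mismatches = length(pos),
      positions = pos,
      three_prime_terminal = mism[n],
      three_prime_window = sum(mism[max(1L, n - window + 1L):n])
    ),
    class = "mismatch_profile"
  )
}

#' @export
print.mismatch_profile <- function(x, ...) {
  cat("<mismatch_profile> ", x$total_mismatches, "/", x$oligo_len,
      " mismatches", sep = "")
  if (x$total_mismatches) {
    cat(" at 5'-offsets ", paste(x$positions, collapse = ","), sep = "")
  }
  cat("; 3'-terminal: ", x$three_prime_terminal,
      "; within 3' window: ", x$three_prime_window, "\n", sep = "")
  invisible(x)
}

#' Per-oligo metrics for an assay table
#'
#' Expands an assay tibble into one row per oligo (forward, reverse,
#' probe) with length, GC content and basic melting temperature.
#'
#' @param assays Assay tibble (see [read_assay_table()]).
#' @return A tibble with columns `name`, `role`, `oligo`, `length`,
#'   `gc_percent`, `tm_basic` (one decimal).
#' @export
oligo_metrics <- function(assays) {
  long <- tidyr::pivot_longer(
    assays[c("name", "forward", "reverse", "probe")],
    cols = c("forward", "reverse", "probe"),
    names_to = "role", values_to = "oligo"
  )
  long <- dplyr::filter(long, !is.na(.data$oligo))
  dplyr::mutate(
    long,
    length = nchar(.data$oligo),
    gc_percent = round_half_up(100 * purrr::map_dbl(.data$oligo, gc_content), 1),
    tm_basic = round_half_up(purrr::map_dbl(.data$oligo, oligo_tm), 1)
  )
}
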