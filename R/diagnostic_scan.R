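# Diagnostic-region scanning. The design question: find alignment
# windows with no variation inside the target species (a primer must
# bind every target haplotype) that maximize the number of differences
# to every non-target panel member. Discrimination is aggregated as the
# worst case (minimum over non-target sequences), because a single
# cross-amplifying species is enough to invalidate a marker.
#
# Coordinates: all tibbles report 1-based inclusive columns.

# per-column summary used by scanning: target variability/eligibility,
# target consensus bits, and a diff indicator matrix for non-targets
panel_column_stats <- function(panel, target_group) {
  tmat <- panel_group_mat(panel, target_group)
  other <- panel$mat[!(panel$groups %in% target_group), , drop = FALSE]
  L <- panel$length

  bits_row <- function(row) unname(IUPAC_BITS[row])
  tbits <- apply(tmat, 1, function(r) unname(IUPAC_BITS[r]))
  # tbits: L x n_target matrix
  tbits <- matrix(tbits, nrow = L)

  # variable: >1 distinct non-gap, non-N symbol among target members
  n_distinct_informative <- apply(tmat, 2, function(col) {
    length(unique(col[!col %in% c("-", "N")]))
  })
  variable <- n_distinct_informative > 1L
  # ineligible for primer placement: any gap or N in a target member
  gap_or_n <- apply(tmat, 2, function(col) any(col %in% c("-", "N")))

  cons_bits <- apply(tbits, 1, function(b) Reduce(bitwOr, b))
  consensus <- BITS_CODE[cons_bits + 1L]

  # diffs: per non-target record, TRUE where its base cannot pair with
  # the target consensus (gaps count as differences)
  diffs <- NULL
  if (nrow(other)) {
    diffs <- t(apply(other, 1, function(r) {
      bitwAnd(unname(IUPAC_BITS[r]), cons_bits) == 0L
    }))
    rownames(diffs) <- rownames(other)
  }

  list(variable = variable, gap_or_n = gap_or_n,
       consensus = consensus, cons_bits = cons_bits, diffs = diffs)
}

#' Variable sites within a group
#'
#' Alignment columns where more than one distinct non-gap, non-N base
#' occurs among the members of a group — the within-group polymorphism
#' that a species-specific primer must avoid.
#'
#' @param panel An [aligned_panel()].
#' @param group Group label (or vector of labels pooled together).
#' @return Integer vector of 1-based column positions; its length is
#'   the variable-site count.
#' @export
variable_sites <- function(panel, group) {
  mat <- panel_group_mat(panel, group)
  if (nrow(mat) == 1L) {
    warning("group of size 1: no within-group variation measurable",
            call. = FALSE)
    return(integer(0))
  }
  which(apply(mat, 2, function(col) {
    length(unique(col[!col %in% c("-", "N")])) > 1L
  }))
}

#' Percent of variable sites
#'
#' @param count Number of variable sites.
#' @param aligned_length Total alignment columns.
#' @return Percentage rounded to 2 decimals (e.g. 40 of 16620 -> 0.24).
#' @export
percent_variable <- function(count, aligned_length) {
  if (aligned_length <= 0) stop("aligned_length must be positive", call. = FALSE)
  round_half_up(100 * count / aligned_length, 2)
}

#' Target-group consensus sequence
#'
#' Per column: the single observed base where the group is invariant,
#' otherwise the minimal IUPAC code covering all observed bases. Gaps
#' are ignored where any member has a base; an all-gap column yields
#' `-`.
#'
#' @param panel An [aligned_panel()].
#' @param group Group label(s).
#' @return IUPAC DNA string of the panel's aligned length.
#' @export
target_consensus <- function(panel, group) {
  mat <- panel_group_mat(panel, group)
  cons <- apply(mat, 2, function(col) {
    obs <- col[col != "-"]
    if (!length(obs)) return("-")
    consensus_code(obs)
  })
  paste(cons, collapse = "")
}

#' Scan a panel for diagnostic windows
#'
#' Slides a window of `win_len` columns across the alignment and
#' scores every window that (a) has no variable sites within the
#' target group and (b) contains no gap or N in any target member (a
#' primer must bind intact target sequence). The score is the
#' worst-case discrimination: the minimum, over non-target records, of
#' the number of window columns whose base cannot pair with the target
#' consensus (non-target gaps count as differences).
#'
#' @param panel An [aligned_panel()].
#' @param target_group Group label(s) of the target taxon.
#' @param win_len Window width in columns (default 20, a typical
#'   primer length).
#' @param window_3p 3'-terminal sub-window size used for the tie-break
#'   counts (default 5).
#' @return A tibble sorted by decreasing score with columns `start`,
#'   `end` (1-based inclusive), `within_target_variable` (always 0 for
#'   emitted windows), `min_nontarget_diffs` (the score),
#'   `min_diffs_3p_fwd` (worst-case diffs in the last `window_3p`
#'   columns — the 3' end of a forward primer laid on this window),
#'   `min_diffs_3p_rev` (first `window_3p` columns — the 3' end of a
#'   reverse primer), `gc_clamp` (G/C count in the last 5 consensus
#'   bases) and `consensus`. Ties are broken by more 3'-window diffs,
#'   then stronger GC clamp, then leftmost start.
#' @export
scan_windows <- function(panel, target_group, win_len = 20L, window_3p = 5L) {
  if (win_len > panel$length) {
    stop("win_len exceeds the panel's aligned length", call. = FALSE)
  }
  window_3p <- min(as.integer(window_3p), as.integer(win_len))
  if (!any(!(panel$groups %in% target_group))) {
    stop("panel has no non-target records to discriminate against",
         call. = FALSE)
  }
  st <- panel_column_stats(panel, target_group)
  L <- panel$length
  n_win <- L - win_len + 1L

  # windowed sums via cumulative sums
  wsum <- function(x) {
    cs <- c(0, cumsum(x))
    cs[(win_len + 1L):(L + 1L)] - cs[1:n_win]
  }
  bad <- wsum(st$variable | st$gap_or_n) > 0
  eligible <- which(!bad)
  if (!length(eligible)) return(empty_windows_tbl())

  nt_ids <- rownames(st$diffs)
  # per non-target: window diff totals and 3' sub-window totals
  totals <- sapply(nt_ids, function(id) wsum(st$diffs[id, ]))
  totals <- matrix(totals, nrow = n_win)
  min_diffs <- apply(totals[eligible, , drop = FALSE], 1, min)

  sub_sum <- function(x, from_off, width) {
    cs <- c(0, cumsum(x))
    starts <- eligible + from_off
    cs[starts + width] - cs[starts]
  }
  # last window_3p columns (forward-primer 3' end)
  fwd3 <- sapply(nt_ids, function(id) {
    sub_sum(st$diffs[id, ], win_len - window_3p, window_3p)
  })
  rev3 <- sapply(nt_ids, function(id) sub_sum(st$diffs[id, ], 0L, window_3p))
  fwd3 <- apply(matrix(fwd3, nrow = length(eligible)), 1, min)
  rev3 <- apply(matrix(rev3, nrow = length(eligible)), 1, min)

  cons_chars <- st$consensus
  w5 <- min(5L, win_len)
  gc_clamp <- vapply(eligible, function(s) {
    tail5 <- cons_chars[(s + win_len - w5):(s + win_len - 1L)]
    sum(bitwAnd(unname(IUPAC_BITS[tail5]), 9L) == 0L &
          unname(IUPAC_BITS[tail5]) != 0L)
  }, numeric(1))

  out <- tibble::tibble(
    start = as.integer(eligible),
    end = as.integer(eligible + win_len - 1L),
    within_target_variable = 0L,
    min_nontarget_diffs = as.integer(min_diffs),
    min_diffs_3p_fwd = as.integer(fwd3),
    min_diffs_3p_rev = as.integer(rev3),
    gc_clamp = as.integer(gc_clamp),
    consensus = vapply(eligible, function(s) {
      paste(cons_chars[s:(s + win_len - 1L)], collapse = "")
    }, character(1))
  )
  dplyr::arrange(out, dplyr::desc(.data$min_nontarget_diffs),
                 dplyr::desc(pmax(.data$min_diffs_3p_fwd,
                                  .data$min_diffs_3p_rev)),
                 dplyr::desc(.data$gc_clamp), .data$start)
}

empty_windows_tbl <- function() {
  tibble::tibble(
    start = integer(0), end = integer(0),
    within_target_variable = integer(0),
    min_nontarget_diffs = integer(0),
    min_diffs_3p_fwd = integer(0), min_diffs_3p_rev = integer(0),
    gc_clamp = integer(0), consensus = character(0)
  )
}

#' Design constraints for candidate assays
#'
#' @param max_amplicon Maximum amplicon length in bp, exclusive
#'   (default 400: short amplicons amplify degraded eDNA more
#'   reliably).
#' @param primer_len Primer (window) length in nt (default 20).
#' @param tm_range Acceptable basic-Tm interval in degrees Celsius for
#'   primers and probes (default `c(45, 75)`, the envelope of the
#'   published carp assay oligos).
#' @param min_3prime_window_diffs Minimum worst-case non-target
#'   mismatch count required inside a primer's 3'-terminal window
#'   (default 0: a 3' mismatch is rewarded in ranking, not required).
#' @param window_3p 3'-terminal window size in bases (default 5).
#' @param max_window_rank Number of top-ranked discriminative windows
#'   considered during pairing (default 200; bounds the search).
#' @return A list of class `design_constraints`.
#' @export
design_constraints <- function(max_amplicon = 400L, primer_len = 20L,
                               tm_range = c(45, 75),
                               min_3prime_window_diffs = 0L,
                               window_3p = 5L, max_window_rank = 200L) {
  stopifnot(max_amplicon > 2 * primer_len, primer_len >= 14,
            length(tm_range) == 2, tm_range[1] < tm_range[2])
  structure(
    list(max_amplicon = as.integer(max_amplicon),
         primer_len = as.integer(primer_len),
         tm_range = as.numeric(tm_range),
         min_3prime_window_diffs = as.integer(min_3prime_window_diffs),
         window_3p = as.integer(window_3p),
         max_window_rank = as.integer(max_window_rank)),
    class = "design_constraints"
  )
}

#' Design candidate species-specific assays
#'
#' Pairs diagnostic windows into conventional-PCR primer pairs (and,
#' for `type = "qPCR"`, adds a hydrolysis probe window strictly between
#' the primers). The forward primer is the target consensus of the
#' upstream window; the reverse primer is the reverse complement of the
#' downstream window's consensus. Both primer windows must be invariant
#' within the target group, discriminative against every non-target
#' (worst-case minimum of one difference or more), and within the Tm
#' range; the amplicon, inclusive of both primers, must be shorter than
#' `constraints$max_amplicon`.
#'
#' Candidates are ranked by the summed worst-case non-target
#' differences of the two primer windows, then by how many primers
#' carry a non-target mismatch within their 3'-terminal window (such
#' mismatches block extension and sharpen specificity), then by GC
#' clamp and coordinate.
#'
#' @param panel An [aligned_panel()].
#' @param target_group Group label(s) of the target taxon.
#' @param constraints A [design_constraints()] list.
#' @param type `"cPCR"` or `"qPCR"` (probe required).
#' @return A tibble of candidates with columns `name`, `target`,
#'   `type`, `forward`, `reverse`, `probe`, coordinates of the three
#'   sites, `amplicon_length`, `score`, `n_3p`, `fwd_tm`, `rev_tm`.
#'   Zero rows (with a message) when no pair satisfies the
#'   constraints.
#' @export
design_assays <- function(panel, target_group,
                          constraints = design_constraints(),
                          type = c("cPCR", "qPCR")) {
  type <- match.arg(type)
  cs <- constraints
  wins <- scan_windows(panel, target_group, win_len = cs$primer_len,
                       window_3p = cs$window_3p)
  disc <- dplyr::filter(wins, .data$min_nontarget_diffs >= 1L)
  disc <- dplyr::mutate(disc, tm = purrr::map_dbl(.data$consensus, oligo_tm))
  disc <- dplyr::filter(disc, .data$tm >= cs$tm_range[1],
                        .data$tm <= cs$tm_range[2],
                        !grepl("-", .data$consensus, fixed = TRUE))
  if (cs$min_3prime_window_diffs > 0L) {
    disc <- dplyr::filter(
      disc,
      pmax(.data$min_diffs_3p_fwd, .data$min_diffs_3p_rev) >=
        cs$min_3prime_window_diffs)
  }
  disc <- utils::head(disc, cs$max_window_rank)
  if (nrow(disc) < 2L) {
    rlang::inform("design_assays: fewer than two qualifying windows; no candidates")
    return(empty_design_tbl())
  }

  pairs <- tidyr::expand_grid(f = seq_len(nrow(disc)), r = seq_len(nrow(disc)))
  pairs <- dplyr::filter(
    pairs,
    disc$start[.data$r] > disc$end[.data$f],
    disc$end[.data$r] - disc$start[.data$f] + 1L < cs$max_amplicon
  )
  if (!nrow(pairs)) {
    rlang::inform("design_assays: no window pair within the amplicon cap")
    return(empty_design_tbl())
  }

  cand <- tibble::tibble(
    fwd_start = disc$start[pairs$f], fwd_end = disc$end[pairs$f],
    rev_start = disc$start[pairs$r], rev_end = disc$end[pairs$r],
    forward = disc$consensus[pairs$f],
    reverse = revcomp(disc$consensus[pairs$r]),
    fwd_tm = disc$tm[pairs$f], rev_tm = disc$tm[pairs$r],
    score = disc$min_nontarget_diffs[pairs$f] +
      disc$min_nontarget_diffs[pairs$r],
    # forward primer 3' end = right edge of its window; reverse primer
    # 3' end = left edge of its window (it reads leftward)
    n_3p = as.integer(disc$min_diffs_3p_fwd[pairs$f] >= 1L) +
      as.integer(disc$min_diffs_3p_rev[pairs$r] >= 1L),
    gc = disc$gc_clamp[pairs$f] + disc$gc_clamp[pairs$r]
  )
  cand$amplicon_length <- cand$rev_end - cand$fwd_start + 1L

  if (type == "qPCR") {
    probe_for <- function(fe, rs) {
      p <- dplyr::filter(disc, .data$start > fe, .data$end < rs)
      if (!nrow(p)) return(NULL)
      p[1, ]  # disc is already ranked
    }
    probes <- purrr::map2(cand$fwd_end, cand$rev_start, probe_for)
    keep <- !vapply(probes, is.null, logical(1))
    cand <- cand[keep, ]
    probes <- probes[keep]
    if (!nrow(cand)) {
      rlang::inform("design_assays: no probe window between any primer pair")
      return(empty_design_tbl())
    }
    cand$probe <- vapply(probes, function(p) p$consensus, character(1))
    cand$probe_start <- vapply(probes, function(p) p$start, integer(1))
    cand$probe_end <- vapply(probes, function(p) p$end, integer(1))
  } else {
    cand$probe <- NA_character_
    cand$probe_start <- NA_integer_
    cand$probe_end <- NA_integer_
  }

  cand <- dplyr::arrange(cand, dplyr::desc(.data$score),
                         dplyr::desc(.data$n_3p), dplyr::desc(.data$gc),
                         .data$fwd_start, .data$rev_start)
  target_label <- paste(target_group, collapse = "+")
  tibble::tibble(
    name = sprintf("%s-cand-%03d", target_label, seq_len(nrow(cand))),
    target = target_label,
    type = type,
    forward = cand$forward, reverse = cand$reverse, probe = cand$probe,
    fwd_start = cand$fwd_start, fwd_end = cand$fwd_end,
    probe_start = cand$probe_start, probe_end = cand$probe_end,
    rev_start = cand$rev_start, rev_end = cand$rev_end,
    amplicon_length = cand$amplicon_length,
    score = cand$score, n_3p = cand$n_3p,
    fwd_tm = round_half_up(cand$fwd_tm, 1),
    rev_tm = round_half_up(cand$rev_tm, 1)
  )
}

empty_design_tbl <- function() {
  tibble::tibble(
    name = character(0), target = character(0), type = character(0),
    forward = character(0), reverse = character(0), probe = character(0),
    fwd_start = integer(0), fwd_end = integer(0),
    probe_start = integer(0), probe_end = integer(0),
    rev_start = integer(0), rev_end = integer(0),
    amplicon_length = integer(0), score = integer(0), n_3p = integer(0),
    fwd_tm = numeric(0), rev_tm = numeric(0)
  )
}
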