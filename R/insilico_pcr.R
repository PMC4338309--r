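# Mismatch-tolerant binding-site search and amplicon prediction.
# Binding model: substitutions only (no primer-template bulges), IUPAC
# bitmask matching, both strands, optionally circular templates
# (mitogenomes are circular, so products may span the origin).
# A site with a mismatch at the primer's 3'-terminal base is excluded
# by default: a terminal mismatch blocks polymerase extension, which is
# precisely the mechanism species-specific primers are designed to
# exploit.

# match counts of `oligo` (5'->3') against the + strand at every start;
# returns data.frame(start, mm) for starts with mm <= max_mm.
# Template is given as a bitmask vector; circular templates are handled
# by the caller via extension.
slide_mismatches <- function(obits, tbits, max_mm) {
  L <- length(obits)
  n_start <- length(tbits) - L + 1L
  if (n_start < 1L) return(integer(0) -> starts)  # empty
  mm <- integer(n_start)
  idx <- seq_len(n_start)
  for (i in seq_len(L)) {
    mm <- mm + as.integer(bitwAnd(obits[i], tbits[idx + i - 1L]) == 0L)
  }
  which(mm <= max_mm) -> starts
  attr(starts, "mm") <- mm[starts]
  starts
}

#' Find primer/probe binding sites on a template
#'
#' Scans both strands of a template for positions where an oligo can
#' bind with at most `max_mm` IUPAC-aware mismatches (substitution-only
#' model). Minus-strand sites are positions where the reverse
#' complement of the oligo matches the plus-strand text.
#'
#' @param oligo IUPAC DNA string (5'->3'), gap-free.
#' @param template Template DNA string (plus strand).
#' @param max_mm Maximum mismatches per site (default 2).
#' @param allow_3prime_mm Keep sites whose mismatch falls on the
#'   oligo's 3'-terminal base (default FALSE: terminal mismatches block
#'   extension).
#' @param circular Treat the template as circular (default FALSE);
#'   sites may then wrap past the end (reported `end` can exceed the
#'   template length).
#' @param strands Strands to search (default both).
#' @param window_3p 3'-terminal window size for the reported mismatch
#'   count (default 5).
#' @param template_id Optional template label carried into the result.
#' @return Tibble with columns `template_id`, `strand`, `start`, `end`
#'   (1-based inclusive template coordinates of the bound stretch),
#'   `mismatches`, `mm_positions` (list column, 0-based offsets from
#'   the oligo 5' end), `three_prime_terminal`, `three_prime_window`.
#' @export
find_sites <- function(oligo, template, max_mm = 2L, allow_3prime_mm = FALSE,
                       circular = FALSE, strands = c("+", "-"),
                       window_3p = 5L, template_id = NA_character_) {
  oligo <- normalize_seq(oligo)
  template <- normalize_seq(template)
  L <- nchar(oligo)
  n <- nchar(template)
  if (L == 0L || n == 0L) stop("oligo and template must be non-empty",
                               call. = FALSE)
  if (L > n) return(empty_sites_tbl())
  obits <- seq_bits(oligo)
  tbits <- seq_bits(template)
  tb_ext <- if (circular && L > 1L) c(tbits, tbits[seq_len(L - 1L)]) else tbits
  n_starts <- if (circular) n else n - L + 1L

  one_strand <- function(strand) {
    qb <- if (strand == "+") obits else seq_bits(revcomp(oligo))
    starts <- slide_mismatches(qb, tb_ext, max_mm)
    starts <- starts[starts <= n_starts]
    if (!length(starts)) return(empty_sites_tbl())
    rows <- purrr::map(starts, function(s) {
      seg <- tb_ext[s:(s + L - 1L)]
      mism <- bitwAnd(qb, seg) == 0L
      # map template offsets back to oligo 5'->3' positions
      if (strand == "+") {
        pos <- which(mism) - 1L
      } else {
        pos <- sort(L - which(mism))
      }
      term <- if (strand == "+") mism[L] else mism[1L]
      w <- min(window_3p, L)
      in_window <- if (strand == "+") mism[(L - w + 1L):L] else mism[1:w]
      tibble::tibble(
        template_id = template_id, strand = strand,
        start = s, end = s + L - 1L,
        mismatches = sum(mism),
        mm_positions = list(pos),
        three_prime_terminal = term,
        three_prime_window = sum(in_window)
      )
    })
    dplyr::bind_rows(rows)
  }

  out <- dplyr::bind_rows(lapply(intersect(c("+", "-"), strands), one_strand))
  if (!allow_3prime_mm && nrow(out)) {
    out <- dplyr::filter(out, !.data$three_prime_terminal)
  }
  out
}

empty_sites_tbl <- function() {
  tibble::tibble(
    template_id = character(0), strand = character(0),
    start = integer(0), end = integer(0), mismatches = integer(0),
    mm_positions = list(), three_prime_terminal = logical(0),
    three_prime_window = integer(0)
  )
}

#' Predict PCR amplicons on a template
#'
#' Pairs forward-primer sites with reverse-primer sites on the opposite
#' strand to enumerate all products up to `max_len`. Product length is
#' inclusive of both primers. Hydrolysis-probe (qPCR) assays
#' additionally require a probe site, on either strand, strictly
#' between the primers' inner boundaries. On circular templates
#' products may span the origin (`spans_origin`).
#'
#' @param assay One assay: a one-row tibble or named list with
#'   `forward`, `reverse`, `type` and (for qPCR) `probe`.
#' @param template Template DNA string (plus strand, ungapped).
#' @param max_mm Maximum mismatches per oligo (default 2).
#' @param max_len Maximum product length in bp (default 2000).
#' @param allow_3prime_mm Keep primer sites with a 3'-terminal mismatch
#'   (default FALSE).
#' @param circular Treat the template as circular (default TRUE, the
#'   mitogenome case).
#' @param template_id Optional template label.
#' @return Tibble with one row per predicted product: primer and probe
#'   site coordinates and mismatch counts, `strand` (product
#'   orientation: `+` means the forward primer binds the plus strand),
#'   `length`, `spans_origin`, `total_mm`.
#' @export
predict_amplicons <- function(assay, template, max_mm = 2L, max_len = 2000L,
                              allow_3prime_mm = FALSE, circular = TRUE,
                              template_id = NA_character_) {
  assay <- as.list(assay)
  template <- normalize_seq(template)
  n <- nchar(template)
  fwd <- normalize_seq(assay$forward)
  rev <- normalize_seq(assay$reverse)
  has_probe <- !is.null(assay$probe) && !is.na(assay$probe)
  if (identical(assay$type, "qPCR") && !has_probe) {
    stop("qPCR assay requires a probe", call. = FALSE)
  }

  fwd_sites <- find_sites(fwd, template, max_mm, allow_3prime_mm,
                          circular = circular, template_id = template_id)
  rev_sites <- find_sites(rev, template, max_mm, allow_3prime_mm,
                          circular = circular, template_id = template_id)
  probe_sites <- if (has_probe) {
    # probes are not extended by the polymerase: no 3'-terminal rule
    find_sites(normalize_seq(assay$probe), template, max_mm,
               allow_3prime_mm = TRUE, circular = circular,
               template_id = template_id)
  } else {
    empty_sites_tbl()
  }

  Lf <- nchar(fwd); Lr <- nchar(rev)

  pair_products <- function(f_tbl, r_tbl, orientation) {
    # orientation "+": forward on +, reverse on -; "-": mirrored
    if (!nrow(f_tbl) || !nrow(r_tbl)) return(NULL)
    grid <- tidyr::expand_grid(fi = seq_len(nrow(f_tbl)),
                               ri = seq_len(nrow(r_tbl)))
    purrr::pmap_dfr(grid, function(fi, ri) {
      fs <- f_tbl[fi, ]; rs <- r_tbl[ri, ]
      if (orientation == "+") {
        left_start <- fs$start; right_end <- rs$end
      } else {
        left_start <- rs$start; right_end <- fs$end
      }
      if (circular) {
        len <- ((right_end - left_start) %% n) + 1L
      } else {
        len <- right_end - left_start + 1L
      }
      if (is.na(len) || len < Lf + Lr || len > max_len) return(NULL)
      spans <- circular && (left_start + len - 1L) > n

      probe_row <- NULL
      if (has_probe) {
        if (!nrow(probe_sites)) return(NULL)
        off <- if (circular) {
          (probe_sites$start - left_start) %% n
        } else {
          probe_sites$start - left_start
        }
        inner_lo <- if (orientation == "+") Lf else Lr
        inner_hi <- if (orientation == "+") len - Lr else len - Lf
        Lp <- probe_sites$end - probe_sites$start + 1L
        ok <- off >= inner_lo & (off + Lp) <= inner_hi
        if (!any(ok)) return(NULL)
        cand <- probe_sites[ok, ]
        probe_row <- cand[which.min(cand$mismatches), ]
      }
      tibble::tibble(
        template_id = template_id,
        strand = orientation,
        fwd_start = fs$start, fwd_end = fs$end, fwd_mm = fs$mismatches,
        rev_start = rs$start, rev_end = rs$end, rev_mm = rs$mismatches,
        probe_start = if (has_probe) probe_row$start else NA_integer_,
        probe_end = if (has_probe) probe_row$end else NA_integer_,
        probe_strand = if (has_probe) probe_row$strand else NA_character_,
        probe_mm = if (has_probe) probe_row$mismatches else NA_integer_,
        length = as.integer(len),
        spans_origin = spans,
        total_mm = fs$mismatches + rs$mismatches +
          (if (has_probe) probe_row$mismatches else 0L)
      )
    })
  }

  out <- dplyr::bind_rows(
    pair_products(dplyr::filter(fwd_sites, .data$strand == "+"),
                  dplyr::filter(rev_sites, .data$strand == "-"), "+"),
    pair_products(dplyr::filter(fwd_sites, .data$strand == "-"),
                  dplyr::filter(rev_sites, .data$strand == "+"), "-")
  )
  if (is.null(out) || !nrow(out)) return(empty_amplicons_tbl())
  dplyr::arrange(out, .data$total_mm, .data$length)
}

empty_amplicons_tbl <- function() {
  tibble::tibble(
    template_id = character(0), strand = character(0),
    fwd_start = integer(0), fwd_end = integer(0), fwd_mm = integer(0),
    rev_start = integer(0), rev_end = integer(0), rev_mm = integer(0),
    probe_start = integer(0), probe_end = integer(0),
    probe_strand = character(0), probe_mm = integer(0),
    length = integer(0), spans_origin = logical(0), total_mm = integer(0)
  )
}

#' Specificity matrix of assays against a species panel
#'
#' Runs [predict_amplicons()] for every assay against every template in
#' a species panel and reports, per cell, whether a product is
#' predicted and the best (minimum) total mismatch count. An assay
#' passes the screen when it amplifies every template of its target
#' species and none of the others — a single cross-amplifying species
#' invalidates a marker.
#'
#' @param assays Assay tibble (see [read_assay_table()]); multi-species
#'   targets are written `"A+B"`.
#' @param templates Tibble with columns `id`, `species`, `seq`
#'   (ungapped plus-strand DNA), or an [aligned_panel()] whose groups
#'   are species labels (gaps are stripped).
#' @param max_mm Maximum mismatches per oligo (default 2).
#' @param circular Circular templates (default TRUE).
#' @param ... Passed on to [predict_amplicons()].
#' @return Tibble with one row per assay x template: `assay`,
#'   `template_id`, `species`, `is_target`, `amplified`, `best_mm`,
#'   `best_length`.
#' @export
specificity_matrix <- function(assays, templates, max_mm = 2L,
                               circular = TRUE, ...) {
  if (inherits(templates, "aligned_panel")) {
    tb <- panel_tbl(templates)
    templates <- tibble::tibble(
      id = tb$id, species = tb$group,
      seq = gsub("-", "", tb$seq, fixed = TRUE)
    )
  }
  if (!nrow(templates) || !nrow(assays)) {
    return(tibble::tibble(
      assay = character(0), template_id = character(0),
      species = character(0), is_target = logical(0),
      amplified = logical(0), best_mm = integer(0),
      best_length = integer(0)
    ))
  }
  grid <- tidyr::expand_grid(ai = seq_len(nrow(assays)),
                             ti = seq_len(nrow(templates)))
  purrr::pmap_dfr(grid, function(ai, ti) {
    assay <- assays[ai, ]
    tmpl <- templates[ti, ]
    prods <- predict_amplicons(assay, tmpl$seq, max_mm = max_mm,
                               circular = circular,
                               template_id = tmpl$id, ...)
    targets <- strsplit(assay$target, "+", fixed = TRUE)[[1]]
    tibble::tibble(
      assay = assay$name,
      template_id = tmpl$id,
      species = tmpl$species,
      is_target = tmpl$species %in% targets,
      amplified = nrow(prods) > 0L,
      best_mm = if (nrow(prods)) min(prods$total_mm) else NA_integer_,
      best_length = if (nrow(prods)) {
        prods$length[which.min(prods$total_mm)]
      } else {
        NA_integer_
      }
    )
  })
}

#' Summarise a specificity matrix per assay
#'
#' @param mat Result of [specificity_matrix()].
#' @return Tibble per assay: `n_target`, `n_target_amplified`,
#'   `n_nontarget`, `n_nontarget_amplified`, `passes` (all targets
#'   amplify, no non-target does).
#' @export
summarise_specificity <- function(mat) {
  dplyr::summarise(
    dplyr::group_by(mat, .data$assay),
    n_target = sum(.data$is_target),
    n_target_amplified = sum(.data$is_target & .data$amplified),
    n_nontarget = sum(!.data$is_target),
    n_nontarget_amplified = sum(!.data$is_target & .data$amplified),
    passes = .data$n_target > 0L &
      .data$n_target_amplified == .data$n_target &
      .data$n_nontarget_amplified == 0L,
    .groups = "drop"
  )
}
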