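# Replicate-level positive calls and detection-rate summaries.
#
# Call rule: a marker is scored positive for a sample when at least one
# of its PCR replicates is positive. A qPCR replicate is positive when
# its amplification curve crossed the fluorescence threshold within the
# cycle limit (default 40 cycles), i.e. its Cq is numeric and <= 40.

#' Positive call over PCR replicates
#'
#' @param cq Replicate results: a numeric vector of Cq values (NA = no
#'   amplification), or a logical vector of per-replicate calls.
#' @param max_cycles Cycle limit (default 40); a numeric Cq above it is
#'   scored negative.
#' @return TRUE if at least one replicate is positive.
#' @export
#' @examples
#' call_sample(c(NA, NA, NA, 38.2))  # TRUE
#' call_sample(c(NA, 41), max_cycles = 40)  # FALSE
call_sample <- function(cq, max_cycles = 40) {
  if (!length(cq)) stop("at least one replicate required", call. = FALSE)
  if (is.logical(cq)) return(any(cq, na.rm = TRUE))
  any(!is.na(cq) & cq > 0 & cq <= max_cycles)
}

#' Derive a detection matrix from a replicate table
#'
#' Applies [call_sample()] per (sample, marker) and pivots to the wide
#' sample x marker layout used by the detection-rate summaries.
#'
#' @param replicates Replicate tibble with columns `sample`, `marker`
#'   and either `cq` (numeric, NA = no amplification) or `positive`
#'   (logical).
#' @param max_cycles Cycle limit for qPCR calls (default 40).
#' @return Wide tibble: `sample` plus one logical column per marker
#'   (NA where a sample x marker cell has no replicates).
#' @export
call_detections <- function(replicates, max_cycles = 40) {
  rep_tbl <- tibble::as_tibble(replicates)
  value_col <- if ("cq" %in% names(rep_tbl)) "cq" else "positive"
  if (!value_col %in% names(rep_tbl)) {
    stop("replicate table needs a 'cq' or 'positive' column", call. = FALSE)
  }
  calls <- dplyr::summarise(
    dplyr::group_by(rep_tbl, .data$sample, .data$marker),
    positive = call_sample(.data[[value_col]], max_cycles = max_cycles),
    .groups = "drop"
  )
  tidyr::pivot_wider(calls, names_from = "marker", values_from = "positive")
}

#' Detection proportions of a dilution series
#'
#' @param series Tibble with columns `n_detected` and `n_replicates`
#'   (typically one row per marker x dilution level).
#' @return `series` with a `proportion` column (2 decimals: 3 of 4
#'   replicates -> 0.75).
#' @export
detection_proportion <- function(series) {
  series <- tibble::as_tibble(series)
  if (any(series$n_replicates <= 0)) {
    stop("n_replicates must be positive", call. = FALSE)
  }
  if (any(series$n_detected < 0 | series$n_detected > series$n_replicates)) {
    stop("n_detected must lie in [0, n_replicates]", call. = FALSE)
  }
  dplyr::mutate(series,
                proportion = round_half_up(.data$n_detected /
                                             .data$n_replicates, 2))
}

#' Replicate-level sensitivity series from a qPCR table
#'
#' Aggregates a replicate table over dilution levels into per-level
#' detection counts and proportions.
#'
#' @param replicates Replicate tibble with `marker`, `dilution` and
#'   `cq` (or `positive`) columns.
#' @param max_cycles Cycle limit (default 40).
#' @return Tibble per (marker, dilution): `n_replicates`, `n_detected`,
#'   `proportion`. Dilution levels keep their order of first
#'   appearance.
#' @export
sensitivity_series <- function(replicates, max_cycles = 40) {
  rep_tbl <- tibble::as_tibble(replicates)
  value_col <- if ("cq" %in% names(rep_tbl)) "cq" else "positive"
  pos <- if (value_col == "cq") {
    !is.na(rep_tbl$cq) & rep_tbl$cq > 0 & rep_tbl$cq <= max_cycles
  } else {
    rep_tbl$positive %in% TRUE
  }
  rep_tbl$..pos <- pos
  rep_tbl$dilution <- factor(rep_tbl$dilution,
                             levels = unique(rep_tbl$dilution))
  out <- dplyr::summarise(
    dplyr::group_by(rep_tbl, .data$marker, .data$dilution),
    n_replicates = dplyr::n(),
    n_detected = sum(.data$..pos),
    .groups = "drop"
  )
  out$dilution <- as.character(out$dilution)
  detection_proportion(out)
}

#' Limit of detection of a dilution series
#'
#' Returns the most dilute level that satisfies the rule with every
#' more-concentrated level also satisfying it (the monotone-prefix
#' rule). Spurious hits at very deep dilutions — single replicates
#' amplifying below an all-negative level, a known signature of PCR
#' stochasticity at around one template copy per reaction — therefore
#' do not extend the reported LOD, although their raw proportions are
#' still in the series.
#'
#' @param series Tibble with columns `dilution` and `proportion`, rows
#'   ordered from most to least concentrated.
#' @param rule `"all_replicates"` (proportion 1), `"majority"`
#'   (proportion >= 0.5) or `"any"` (proportion > 0).
#' @return The dilution label at the LOD, or NA if no level qualifies.
#' @export
#' @examples
#' s <- data.frame(dilution = paste0("10^-", 1:7),
#'                 proportion = c(1, 1, 1, 1, 0, 0, 0))
#' lod_level(s)  # "10^-4"
lod_level <- function(series, rule = c("all_replicates", "majority", "any")) {
  rule <- match.arg(rule)
  series <- tibble::as_tibble(series)
  ok <- switch(rule,
               all_replicates = series$proportion >= 1,
               majority = series$proportion >= 0.5,
               any = series$proportion > 0)
  run <- cumprod(as.integer(ok))  # monotone prefix
  if (!any(run == 1L)) return(NA_character_)
  as.character(series$dilution[max(which(run == 1L))])
}

#' Per-marker detection counts and rates
#'
#' Column sums of a detection matrix. NA cells (marker not tested for
#' that sample) are excluded from both the count and the denominator,
#' so markers tested on fewer samples report against their own n.
#'
#' @param matrix Wide detection tibble (`sample` + logical marker
#'   columns).
#' @return Tibble per marker: `positives`, `n`, `rate_percent`
#'   (round-half-up integer: 28 of 44 -> 64).
#' @export
marker_detection_counts <- function(matrix) {
  mat <- tibble::as_tibble(matrix)
  if (!nrow(mat)) stop("detection matrix is empty", call. = FALSE)
  markers <- setdiff(names(mat), "sample")
  purrr::map_dfr(markers, function(m) {
    v <- mat[[m]]
    n <- sum(!is.na(v))
    pos <- sum(v, na.rm = TRUE)
    tibble::tibble(
      marker = m, positives = pos, n = n,
      rate_percent = as.integer(round_half_up(100 * pos / n))
    )
  })
}

#' Multi-marker union and complementarity
#'
#' How much does a combination of markers add over its best member?
#' Reports the union count (samples positive for at least one marker
#' of the subset), per-marker exclusive counts (samples positive for
#' exactly one subset marker), and the any-marker total over the full
#' matrix for context.
#'
#' @param matrix Wide detection tibble.
#' @param markers Character vector of marker columns to combine.
#' @return A list of class `marker_combination`: `markers`,
#'   `union_count`, `exclusive` (tibble marker/exclusive_count),
#'   `any_marker_total`, `n_samples`.
#' @export
combine_markers <- function(matrix, markers) {
  mat <- tibble::as_tibble(matrix)
  missing_m <- setdiff(markers, names(mat))
  if (length(missing_m)) {
    stop("marker(s) not in matrix: ", paste(missing_m, collapse = ", "),
         call. = FALSE)
  }
  sub <- as.matrix(mat[markers])
  sub[is.na(sub)] <- FALSE
  n_pos <- rowSums(sub)
  all_m <- as.matrix(mat[setdiff(names(mat), "sample")])
  all_m[is.na(all_m)] <- FALSE
  structure(
    list(
      markers = markers,
      union_count = sum(n_pos >= 1L),
      exclusive = tibble::tibble(
        marker = markers,
        exclusive_count = vapply(seq_along(markers), function(i) {
          sum(sub[, i] & n_pos == 1L)
        }, numeric(1))
      ),
      any_marker_total = sum(rowSums(all_m) >= 1L),
      n_samples = nrow(mat)
    ),
    class = "marker_combination"
  )
}

#' @export
print.marker_combination <- function(x, ...) {
  cat("<marker_combination> ", paste(x$markers, collapse = " + "), "\n",
      "union: ", x$union_count, " of ", x$n_samples, " samples (",
      x$any_marker_total, " positive for any marker in the matrix)\n",
      sep = "")
  excl <- sprintf("%s only: %d", x$exclusive$marker,
                  x$exclusive$exclusive_count)
  cat(paste(excl, collapse = "; "), "\n")
  invisible(x)
}

#' Check designated negative samples for false positives
#'
#' @param matrix Wide detection tibble.
#' @param negative_samples Sample ids expected to be negative for every
#'   marker (e.g. samples from waters outside the species' range).
#' @return Tibble of violations (`sample`, `marker`); zero rows means
#'   the check passes.
#' @export
false_positive_check <- function(matrix, negative_samples) {
  mat <- tibble::as_tibble(matrix)
  if (!length(negative_samples)) {
    return(tibble::tibble(sample = character(0), marker = character(0)))
  }
  missing_s <- setdiff(negative_samples, mat$sample)
  if (length(missing_s)) {
    stop("negative sample(s) not in matrix: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  }
  sub <- mat[mat$sample %in% negative_samples, ]
  long <- tidyr::pivot_longer(sub, cols = -"sample",
                              names_to = "marker", values_to = "positive")
  viol <- dplyr::filter(long, .data$positive %in% TRUE)
  dplyr::select(viol, "sample", "marker")
}

#' Plot a sensitivity (dilution) series
#'
#' Detection proportion per dilution level for each marker.
#'
#' @param series Tibble with `marker`, `dilution`, `proportion`
#'   (dilution levels plotted in order of appearance).
#' @return A ggplot object.
#' @export
plot_dilution_series <- function(series) {
  series <- tibble::as_tibble(series)
  series$dilution <- factor(series$dilution,
                            levels = unique(series$dilution))
  ggplot2::ggplot(series,
                  ggplot2::aes(x = .data$dilution, y = .data$proportion,
                               group = .data$marker,
                               colour = .data$marker)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "dilution", y = "detection proportion",
                  title = "Dilution-series sensitivity")
}

#' Plot a specificity matrix
#'
#' Assay x species tile plot of predicted amplification.
#'
#' @param mat Result of [specificity_matrix()].
#' @return A ggplot object.
#' @export
plot_specificity <- function(mat) {
  ggplot2::ggplot(mat,
                  ggplot2::aes(x = .data$template_id, y = .data$assay,
                               fill = .data$amplified)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey95")) +
    ggplot2::labs(x = "template", y = "assay",
                  title = "In-silico specificity screen") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
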