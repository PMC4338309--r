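#' Construct an aligned sequence panel
#'
#' An aligned panel holds a multiple sequence alignment (equal-length,
#' gapped IUPAC DNA strings) together with a group label for every
#' record, e.g. target species versus a panel of non-target relatives.
#' It is the input to [variable_sites()], [scan_windows()] and
#' [design_assays()].
#'
#' @param seqs Named character vector of aligned sequences (names are
#'   record ids, e.g. GenBank accessions). Lowercase input is
#'   normalized to uppercase.
#' @param groups Named character vector mapping every record id to a
#'   group label, or a data frame with columns `id` and `group`.
#' @return An object of class `aligned_panel`: a list with elements
#'   `mat` (character matrix, one row per record, one column per
#'   alignment column), `ids`, `groups` (named character vector) and
#'   `length` (number of alignment columns).
#' @export
#' @examples
#' p <- aligned_panel(
#'   c(a1 = "ACGTACGT", a2 = "ACGTACGT", b1 = "ACGTACGA"),
#'   c(a1 = "A", a2 = "A", b1 = "B")
#' )
#' p$length
aligned_panel <- function(seqs, groups) {
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop("`seqs` must be a named character vector", call. = FALSE)
  }
  ids <- names(seqs)
  if (anyDuplicated(ids)) {
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- stats::setNames(normalize_seq(seqs), ids)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    ref_len <- lens[[1]]
    bad <- ids[lens != ref_len][1]
    stop("aligned records must all have the same length; record '", bad,
         "' has ", lens[[bad]], " columns but '", ids[[1]], "' has ",
         ref_len, call. = FALSE)
  }
  if (any(lens == 0L)) stop("sequences must be non-empty", call. = FALSE)

  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$group), groups$id)
  }
  missing_ids <- setdiff(ids, names(groups))
  if (length(missing_ids)) {
    stop("group_map does not cover record(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(groups), ids)
  if (length(unknown)) {
    stop("group_map refers to unknown record(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  groups <- groups[ids]

  mat <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  rownames(mat) <- ids
  structure(
    list(mat = mat, ids = ids, groups = groups, length = unname(lens[[1]])),
    class = "aligned_panel"
  )
}

#' @export
print.aligned_panel <- function(x, ...) {
  cat("<aligned_panel> ", length(x$ids), " records x ", x$length,
      " columns\n", sep = "")
  tab <- table(x$groups)
  cat("groups: ",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.aligned_panel <- function(x, ...) {
  as.data.frame(panel_tbl(x))
}

#' Panel records as a tibble
#'
#' @param panel An [aligned_panel()].
#' @return A tibble with columns `id`, `group`, `seq`.
#' @export
panel_tbl <- function(panel) {
  stopifnot(inherits(panel, "aligned_panel"))
  tibble::tibble(
    id = panel$ids,
    group = unname(panel$groups),
    seq = unname(apply(panel$mat, 1, paste, collapse = ""))
  )
}

# records of one or several groups as a sub-matrix
panel_group_mat <- function(panel, group) {
  keep <- panel$groups %in% group
  if (!any(keep)) stop("no records in group(s): ",
                       paste(group, collapse = ", "), call. = FALSE)
  panel$mat[keep, , drop = FALSE]
}

# ungapped sequence of one record (for use as a PCR template)
panel_template <- function(panel, id) {
  s <- paste(panel$mat[id, ], collapse = "")
  gsub("-", "", s, fixed = TRUE)
}
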