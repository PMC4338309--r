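# File formats: aligned FASTA for panels (Biostrings), TSV for assay
# tables, CSV for qPCR replicate tables and detection matrices.
# Coordinates in all files and returned tibbles are 1-based inclusive.
# The token "no-amp" in a Cq column denotes a reaction that never
# crossed the fluorescence threshold; it is read as NA.

#' Read an aligned FASTA file into an aligned panel
#'
#' @param path Path to a FASTA file of equal-length aligned sequences
#'   (gap character `-`).
#' @param group_map Named character vector mapping every record id to a
#'   group label, or a data frame with columns `id`, `group`.
#' @return An [aligned_panel()].
#' @export
read_aligned_fasta <- function(path, group_map) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  aligned_panel(seqs, group_map)
}

#' Write an aligned panel to FASTA
#'
#' @param panel An [aligned_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(panel, path) {
  tb <- panel_tbl(panel)
  ss <- Biostrings::DNAStringSet(stats::setNames(tb$seq, tb$id))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read an assay definition table
#'
#' Reads a TSV with columns `name`, `target`, `type`, `forward`,
#' `reverse`, `probe`, `length`. Oligo sequences are normalized to
#' uppercase (published primer tables are sometimes lowercase).
#' `type` is `cPCR` (no probe) or `qPCR` (hydrolysis probe required:
#' a TaqMan assay needs specific binding at three sites).
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `name`, `target`, `type`, `forward`,
#'   `reverse`, `probe` (NA where absent), `reported_length` (NA where
#'   absent).
#' @export
read_assay_table <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        na = c("", "NA"))
  required <- c("name", "target", "type", "forward", "reverse")
  missing_cols <- setdiff(required, names(tb))
  if (length(missing_cols)) {
    stop("assay table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"probe" %in% names(tb)) tb$probe <- NA_character_
  if (!"length" %in% names(tb)) tb$length <- NA_character_
  out <- tibble::tibble(
    name = tb$name,
    target = tb$target,
    type = tb$type,
    forward = normalize_seq(tb$forward),
    reverse = normalize_seq(tb$reverse),
    probe = {
      pr <- tb$probe
      pr[!is.na(pr)] <- normalize_seq(pr[!is.na(pr)])
      pr
    },
    reported_length = suppressWarnings(as.integer(tb$length))
  )
  validate_assays(out)
  out
}

validate_assays <- function(assays) {
  if (!all(assays$type %in% c("cPCR", "qPCR"))) {
    stop("assay type must be 'cPCR' or 'qPCR'", call. = FALSE)
  }
  bad_q <- assays$type == "qPCR" & is.na(assays$probe)
  if (any(bad_q)) {
    stop("qPCR assay(s) lacking a probe: ",
         paste(assays$name[bad_q], collapse = ", "), call. = FALSE)
  }
  bad_c <- assays$type == "cPCR" & !is.na(assays$probe)
  if (any(bad_c)) {
    stop("cPCR assay(s) must not carry a probe: ",
         paste(assays$name[bad_c], collapse = ", "), call. = FALSE)
  }
  oligos <- c(assays$forward, assays$reverse, assays$probe[!is.na(assays$probe)])
  if (any(nchar(oligos) < 14L)) {
    stop("all assay oligos must be at least 14 nt", call. = FALSE)
  }
  invisible(assays)
}

#' Write an assay definition table
#'
#' @param assays Assay tibble as returned by [read_assay_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_assay_table <- function(assays, path) {
  out <- tibble::tibble(
    name = assays$name, target = assays$target, type = assays$type,
    forward = assays$forward, reverse = assays$reverse,
    probe = assays$probe, length = assays$reported_length
  )
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Read a qPCR replicate table
#'
#' CSV with columns `sample`, `marker`, `replicate`, `cq` and optional
#' `dilution`. The Cq cell is a cycle number or the token `no-amp` for
#' a reaction that never crossed the fluorescence threshold (read as
#' NA).
#'
#' @param path Path to the CSV.
#' @return A tibble with `cq` numeric (NA = no amplification).
#' @export
read_qpcr_table <- function(path) {
  tb <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        na = c("", "NA"))
  required <- c("sample", "marker", "replicate", "cq")
  missing_cols <- setdiff(required, names(tb))
  if (length(missing_cols)) {
    stop("qPCR table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cq_raw <- tb$cq
  cq <- suppressWarnings(as.numeric(ifelse(cq_raw == "no-amp", NA, cq_raw)))
  bad <- !is.na(cq_raw) & cq_raw != "no-amp" & is.na(cq)
  if (any(bad)) {
    stop("unparseable Cq value(s): ",
         paste(unique(cq_raw[bad]), collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(cq) & cq <= 0)) {
    stop("numeric Cq values must be positive", call. = FALSE)
  }
  out <- tibble::tibble(
    sample = tb$sample,
    marker = tb$marker,
    replicate = as.integer(tb$replicate),
    cq = cq
  )
  if ("dilution" %in% names(tb)) out$dilution <- tb$dilution
  dup <- duplicated(out[c("sample", "marker", "replicate")])
  if (any(dup)) {
    stop("duplicate (sample, marker, replicate) row(s)", call. = FALSE)
  }
  out
}

#' Write a qPCR replicate table
#'
#' NA Cq values are written as the token `no-amp`.
#'
#' @param tbl Replicate tibble (see [read_qpcr_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_qpcr_table <- function(tbl, path) {
  out <- tbl
  out$cq <- ifelse(is.na(out$cq), "no-amp", format(out$cq, trim = TRUE))
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a detection matrix
#'
#' CSV with a `sample` column followed by one 0/1 column per marker;
#' empty cells become NA (marker not tested for that sample).
#'
#' @param path Path to the CSV.
#' @return A wide tibble: `sample` plus one logical column per marker.
#' @export
read_detection_matrix <- function(path) {
  tb <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        na = c("", "NA"))
  if (names(tb)[1] != "sample") {
    stop("first column of a detection matrix must be 'sample'",
         call. = FALSE)
  }
  markers <- names(tb)[-1]
  out <- tibble::tibble(sample = tb$sample)
  for (m in markers) {
    v <- tb[[m]]
    if (any(!is.na(v) & !v %in% c("0", "1", "TRUE", "FALSE"))) {
      stop("detection matrix cells must be 0/1, column: ", m, call. = FALSE)
    }
    out[[m]] <- !is.na(v) & v %in% c("1", "TRUE")
    out[[m]][is.na(v)] <- NA
  }
  out
}

#' Write a detection matrix
#'
#' @param mat Wide detection tibble (see [read_detection_matrix()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_detection_matrix <- function(mat, path) {
  out <- mat
  for (m in names(out)[-1]) out[[m]] <- as.integer(out[[m]])
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Path to a packaged data file
#'
#' Convenience wrapper around `system.file()` for the tables shipped
#' with the package, e.g. `"table3_assays.tsv"` (the published carp
#' assay panel) and `"qapp_markers.tsv"` (the monitoring-program
#' markers it was compared against).
#'
#' @param file File name under `extdata/`; if missing, lists available
#'   files.
#' @return A file path, or a vector of file names.
#' @export
ednassay_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "ednassay"))
  } else {
    path <- system.file("extdata", file, package = "ednassay")
    if (path == "") stop("no packaged file named '", file, "'", call. = FALSE)
    path
  }
}
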