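# Independent brute-force oracles. These deliberately avoid the
# package's bitmask machinery: IUPAC codes are expanded to explicit
# base sets, matching is set intersection, and scans are plain loops.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  `-` = character(0)
)

naive_match <- function(a, b) {
  length(intersect(IUPAC_SETS[[a]], IUPAC_SETS[[b]])) > 0
}

naive_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
            S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
            H = "D", V = "B", N = "N", `-` = "-")
  paste(rev(unname(comp[strsplit(s, "")[[1]]])), collapse = "")
}

# per-position mismatch offsets (0-based) of oligo vs equal-length window
naive_mismatch_positions <- function(oligo, window) {
  o <- strsplit(oligo, "")[[1]]
  w <- strsplit(window, "")[[1]]
  out <- integer(0)
  for (i in seq_along(o)) {
    if (!naive_match(o[i], w[i])) out <- c(out, i - 1L)
  }
  out
}

# exhaustive linear-template site search, both strands
naive_find_sites <- function(oligo, template, max_mm, allow_3prime_mm = FALSE) {
  L <- nchar(oligo)
  n <- nchar(template)
  res <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") oligo else naive_revcomp(oligo)
    qc <- strsplit(q, "")[[1]]
    tc <- strsplit(template, "")[[1]]
    for (s in seq_len(n - L + 1)) {
      mm <- 0L; mism <- logical(L)
      for (i in seq_len(L)) {
        if (!naive_match(qc[i], tc[s + i - 1])) { mm <- mm + 1L; mism[i] <- TRUE }
      }
      if (mm > max_mm) next
      terminal <- if (strand == "+") mism[L] else mism[1]
      if (!allow_3prime_mm && terminal) next
      res[[length(res) + 1]] <- data.frame(strand = strand, start = s,
                                           end = s + L - 1, mismatches = mm)
    }
  }
  do.call(rbind, res)
}

# exhaustive diagnostic-window scan: for every window with no
# within-target variation and no target gap/N, the minimum over
# non-target records of per-column differences to the target consensus
naive_scan <- function(panel, target_group, win_len) {
  tb <- panel_tbl(panel)
  tgt <- strsplit(tb$seq[tb$group %in% target_group], "")
  oth <- strsplit(tb$seq[!tb$group %in% target_group], "")
  L <- nchar(tb$seq[1])
  out <- list()
  for (s in seq_len(L - win_len + 1)) {
    cols <- s:(s + win_len - 1)
    ok <- TRUE
    cons <- character(win_len)
    for (j in seq_along(cols)) {
      obs <- vapply(tgt, `[[`, character(1), cols[j])
      if (any(obs %in% c("-", "N"))) { ok <- FALSE; break }
      if (length(unique(obs[!obs %in% c("-", "N")])) > 1) { ok <- FALSE; break }
      # minimal covering code
      un <- sort(unique(unlist(IUPAC_SETS[obs])))
      cons[j] <- names(IUPAC_SETS)[vapply(IUPAC_SETS, function(x) {
        setequal(sort(x), un)
      }, logical(1))][1]
    }
    if (!ok) next
    mins <- Inf
    for (o in oth) {
      d <- 0L
      for (j in seq_along(cols)) {
        if (!naive_match(cons[j], o[[cols[j]]])) d <- d + 1L
      }
      mins <- min(mins, d)
    }
    out[[length(out) + 1]] <- data.frame(start = s, end = s + win_len - 1,
                                         min_nontarget_diffs = mins)
  }
  do.call(rbind, out)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

table3_assays <- function() {
  read_assay_table(ednassay_example("table3_assays.tsv"))
}

# synthetic template carrying one perfect product of a given length for
# an assay: forward ... (probe) ... revcomp(reverse), padded both sides
embed_assay_template <- function(assay, product_length, pad = 150) {
  fwd <- assay$forward; rev <- assay$reverse
  inner_len <- product_length - nchar(fwd) - nchar(rev)
  stopifnot(inner_len >= 0)
  inner <- if (!is.na(assay$probe)) {
    p <- assay$probe
    stopifnot(inner_len >= nchar(p) + 2)
    left <- (inner_len - nchar(p)) %/% 2
    paste0(random_dna(left), p, random_dna(inner_len - nchar(p) - left))
  } else {
    random_dna(inner_len)
  }
  paste0(random_dna(pad), fwd, inner, revcomp(rev), random_dna(pad))
}

# fast exhaustive oracle for non-degenerate (ACGT-only) inputs:
# enumerate every start on both strands and count plain character
# inequalities; independent of the package's bitmask kernel
exhaustive_sites_acgt <- function(oligo, template, max_mm,
                                  allow_3prime_mm = FALSE) {
  tc <- strsplit(template, "")[[1]]
  L <- nchar(oligo)
  n <- length(tc)
  res <- list()
  for (strand in c("+", "-")) {
    qc <- strsplit(if (strand == "+") oligo else naive_revcomp(oligo),
                   "")[[1]]
    for (s in seq_len(n - L + 1)) {
      seg <- tc[s:(s + L - 1)]
      mism <- qc != seg
      if (sum(mism) > max_mm) next
      terminal <- if (strand == "+") mism[L] else mism[1]
      if (!allow_3prime_mm && terminal) next
      res[[length(res) + 1]] <- data.frame(strand = strand, start = s,
                                           mismatches = sum(mism))
    }
  }
  do.call(rbind, res)
}
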