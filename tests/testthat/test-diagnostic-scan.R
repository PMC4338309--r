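make_panel <- function(seqs, groups) {
  aligned_panel(stats::setNames(seqs, names(groups)), groups)
}

test_that("identical sequences have no variable sites", {
  seqs <- rep(strrep("ACGT", 25), 5)
  names(seqs) <- paste0("s", 1:5)
  p <- aligned_panel(seqs, stats::setNames(rep("A", 5), names(seqs)))
  expect_length(variable_sites(p, "A"), 0)
})

test_that("planted column mutations are recovered exactly", {
  set.seed(7)
  ref <- strsplit(random_dna(1000), "")[[1]]
  planted <- sort(sample(1000, 7))
  seqs <- replicate(10, ref, simplify = FALSE)
  for (k in seq_along(planted)) {
    col <- planted[k]
    m <- (k %% 10) + 1
    seqs[[m]][col] <- setdiff(c("A", "C", "G", "T"), ref[col])[1]
  }
  seqs <- vapply(seqs, paste, character(1), collapse = "")
  names(seqs) <- paste0("s", 1:10)
  p <- aligned_panel(seqs, stats::setNames(rep("G1", 10), names(seqs)))
  expect_equal(variable_sites(p, "G1"), planted)
})

test_that("a singleton group yields no variable sites, with a warning", {
  p <- make_panel(c("ACGT", "AGGT"), c(a = "A", b = "B"))
  expect_warning(v <- variable_sites(p, "A"), "size 1")
  expect_length(v, 0)
})

test_that("variable sites of a pooled group dominate the subgroups", {
  set.seed(11)
  g <- generate_panel(ref_length = 500, n_target_a = 4, n_target_b = 4,
                      n_nontarget = 2, seed = 11)
  va <- variable_sites(g$panel, "A")
  vb <- variable_sites(g$panel, "B")
  vab <- variable_sites(g$panel, c("A", "B"))
  expect_gte(length(vab), max(length(va), length(vb)))
  expect_true(all(va %in% vab))
  expect_true(all(vb %in% vab))
})

test_that("percent_variable reproduces the printed mitogenome figures", {
  expect_equal(percent_variable(40, 16620), 0.24)
  expect_equal(percent_variable(34, 16620), 0.20)
  expect_equal(percent_variable(823, 16620), 4.95)
  expect_equal(percent_variable(0, 16620), 0)
  expect_error(percent_variable(1, 0), "positive")
})

test_that("target consensus uses minimal covering IUPAC codes", {
  p <- make_panel(c("AAC", "AAC"), c(a = "A", b = "A"))
  expect_equal(target_consensus(p, "A"), "AAC")
  p2 <- make_panel(c("AACA", "GACA"), c(a = "A", b = "A"))
  expect_equal(target_consensus(p2, "A"), "RACA")
  # random small panels match per-column set cover
  set.seed(21)
  for (rep in 1:10) {
    n <- 4; L <- 12
    seqs <- vapply(1:n, function(i) random_dna(L), character(1))
    names(seqs) <- paste0("s", 1:n)
    p3 <- aligned_panel(seqs, stats::setNames(rep("G", n), names(seqs)))
    cons <- strsplit(target_consensus(p3, "G"), "")[[1]]
    mat <- do.call(rbind, strsplit(seqs, ""))
    for (j in seq_len(L)) {
      expect_true(setequal(IUPAC_SETS[[cons[j]]], unique(mat[, j])))
    }
  }
})

test_that("windows score zero when target and non-target are identical", {
  s <- strrep("ACGT", 30)
  p <- make_panel(c(s, s, s), c(t1 = "T", t2 = "T", n1 = "N1"))
  w <- scan_windows(p, "T", win_len = 20)
  expect_true(all(w$min_nontarget_diffs == 0))
  expect_true(all(w$within_target_variable == 0))
})

test_that("a planted diagnostic window ranks first with its planted score", {
  set.seed(33)
  ref <- strsplit(random_dna(400), "")[[1]]
  # non-target differs from target only at 3 columns inside [200, 224]
  diffs <- c(205, 212, 219)
  nt <- ref
  for (col in diffs) nt[col] <- setdiff(c("A", "C", "G", "T"), ref[col])[1]
  p <- make_panel(
    vapply(list(ref, ref, nt), paste, character(1), collapse = ""),
    c(t1 = "T", t2 = "T", n1 = "N1")
  )
  w <- scan_windows(p, "T", win_len = 25)
  expect_equal(max(w$min_nontarget_diffs), 3)
  top <- w[1, ]
  expect_lte(top$start, min(diffs))
  expect_gte(top$end, max(diffs))
  expect_equal(top$min_nontarget_diffs, 3)
})

test_that("windows with target gaps or variation are never emitted", {
  seqs <- c(t1 = paste0(strrep("A", 10), "-", strrep("A", 19)),
            t2 = strrep("A", 30),
            n1 = strrep("C", 30))
  p <- aligned_panel(seqs, c(t1 = "T", t2 = "T", n1 = "N1"))
  w <- scan_windows(p, "T", win_len = 8)
  # column 11 is gapped in a target member: no emitted window covers it
  expect_true(all(w$end < 11 | w$start > 11))
  expect_true(all(w$within_target_variable == 0))
})

test_that("scan_windows equals the exhaustive window enumeration", {
  set.seed(55)
  for (rep in 1:8) {
    L <- sample(40:60, 1)
    n_t <- sample(2:3, 1); n_n <- sample(1:3, 1)
    base <- strsplit(random_dna(L), "")[[1]]
    seqs <- character(0)
    for (i in seq_len(n_t)) {
      s <- base
      if (runif(1) < 0.5) {  # occasional within-target variant
        col <- sample(L, 1)
        s[col] <- sample(setdiff(c("A", "C", "G", "T"), s[col]), 1)
      }
      seqs <- c(seqs, paste(s, collapse = ""))
    }
    for (i in seq_len(n_n)) {
      s <- base
      cols <- sample(L, sample(2:6, 1))
      for (col in cols) s[col] <- sample(setdiff(c("A", "C", "G", "T"), s[col]), 1)
      seqs <- c(seqs, paste(s, collapse = ""))
    }
    names(seqs) <- c(paste0("t", seq_len(n_t)), paste0("n", seq_len(n_n)))
    groups <- stats::setNames(c(rep("T", n_t), paste0("N", seq_len(n_n))),
                              names(seqs))
    p <- aligned_panel(seqs, groups)
    win_len <- sample(8:15, 1)
    got <- scan_windows(p, "T", win_len = win_len)
    want <- naive_scan(p, "T", win_len)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      got <- got[order(got$start), ]
      expect_equal(got$start, want$start)
      expect_equal(got$min_nontarget_diffs, want$min_nontarget_diffs)
    }
  }
})

test_that("adding a non-target sequence never increases any window score", {
  set.seed(77)
  g <- generate_panel(ref_length = 500, n_target_a = 4, n_target_b = 0,
                      n_nontarget = 3, seed = 77)
  tb <- panel_tbl(g$panel)
  w_all <- scan_windows(g$panel, "A", win_len = 20)
  drop_one <- tb[tb$id != "NT3", ]
  p_small <- aligned_panel(stats::setNames(drop_one$seq, drop_one$id),
                           stats::setNames(drop_one$group, drop_one$id))
  w_small <- scan_windows(p_small, "A", win_len = 20)
  j <- dplyr::inner_join(w_all, w_small, by = "start",
                         suffix = c("_all", "_small"))
  expect_true(all(j$min_nontarget_diffs_all <= j$min_nontarget_diffs_small))
})

test_that("designed primer pairs respect the amplicon-length convention", {
  # divergence confined to two planted windows, so every discriminative
  # primer site is known by construction
  # one planted difference per region, so a primer pair must straddle
  # the two regions: the candidate geometry is fully known
  g <- generate_panel(ref_length = 700, n_target_a = 5, n_target_b = 0,
                      n_nontarget = 3, within_rate = 0, between_rate = 0,
                      n_diagnostic_windows = 2, window_len = 20,
                      diffs_per_window = 1,
                      window_starts = c(200, 375), seed = 99)
  wide_tm <- design_constraints(tm_range = c(0, 100))
  cand <- design_assays(g$panel, "A", wide_tm)
  expect_gt(nrow(cand), 0)
  expect_equal(cand$amplicon_length, cand$rev_end - cand$fwd_start + 1L)
  expect_true(all(cand$amplicon_length < 400))
  expect_true(all(cand$score >= 2))
  # primers overlap the planted diagnostic regions
  expect_true(all(cand$fwd_end >= 200 & cand$fwd_start <= 219))
  expect_true(all(cand$rev_end >= 375 & cand$rev_start <= 394))
  # reverse primer is the reverse complement of the panel consensus there
  top <- cand[1, ]
  cons <- target_consensus(g$panel, "A")
  expect_equal(top$forward, substr(cons, top$fwd_start, top$fwd_end))
  expect_equal(top$reverse,
               revcomp(substr(cons, top$rev_start, top$rev_end)))

  # a tight amplicon cap (smaller than the planted window spacing)
  # empties the candidate list
  tight <- design_constraints(max_amplicon = 100, tm_range = c(0, 100))
  expect_equal(nrow(suppressMessages(design_assays(g$panel, "A", tight))), 0)
})

test_that("qPCR design places the probe strictly between the primers", {
  g <- generate_panel(ref_length = 900, n_target_a = 5, n_target_b = 0,
                      n_nontarget = 3, within_rate = 0, between_rate = 0,
                      n_diagnostic_windows = 3, window_len = 25,
                      diffs_per_window = 3,
                      window_starts = c(300, 400, 500), seed = 100)
  wide_tm <- design_constraints(tm_range = c(0, 100))
  cand <- design_assays(g$panel, "A", wide_tm, type = "qPCR")
  expect_gt(nrow(cand), 0)
  expect_true(all(!is.na(cand$probe)))
  expect_true(all(cand$probe_start > cand$fwd_end))
  expect_true(all(cand$probe_end < cand$rev_start))
})
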