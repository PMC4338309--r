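# Seeded generators for synthetic mitogenome panels and qPCR runs.
#
# The panel generator emulates the variation structure of closely
# related carp mitogenomes: very little within-species variation
# (defaults 0.2% of columns, matching the ~0.20-0.24% observed within
# each species), moderate between-species divergence (default 5%,
# matching the ~4.95% observed between the two target species), and
# clustered species-diagnostic differences planted as windows where
# every non-target sequence differs from the target at the same few
# columns. Substitutions only — no indels — so the alignment length
# equals the genome length, as in the real data. What it does not
# emulate: phylogenetic rate heterogeneity, hotspots, base
# composition bias, or eDNA degradation.

ALT_BASE <- c(A = "G", C = "T", G = "A", T = "C")  # transitions

rand_base_not <- function(current) {
  vapply(current, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
         character(1))
}

#' Generate a synthetic aligned mitogenome panel
#'
#' Builds a reference sequence, derives two target species groups and a
#' set of non-target species from it, plants within-group variable
#' sites at `within_rate`, between-species divergence at
#' `between_rate`, and `n_diagnostic_windows` clustered
#' target-diagnostic difference windows (every non-member of
#' `target_group` differs from the target at `diffs_per_window` shared
#' columns inside each window). Returns the panel together with a truth
#' record listing every planted feature, so recovery can be verified
#' against ground truth.
#'
#' @param ref_length Alignment length in bp (default 2000).
#' @param n_target_a,n_target_b Members of target groups `"A"` and
#'   `"B"` (defaults 6 and 4; set `n_target_b = 0` for a single target
#'   species).
#' @param n_nontarget Non-target species (default 5), labelled
#'   `"NT1"`, `"NT2"`, ...
#' @param within_rate Fraction of columns made variable within each
#'   target group (default 0.002).
#' @param between_rate Per-column substitution rate between species
#'   (default 0.05).
#' @param n_diagnostic_windows Diagnostic windows planted for group
#'   `"A"` (default 2).
#' @param window_len Planted window width (default 25).
#' @param diffs_per_window Clustered diagnostic differences per window
#'   (default 3).
#' @param window_starts Optional fixed 1-based window start positions
#'   (length `n_diagnostic_windows`); by default windows are spread
#'   evenly across the alignment.
#' @param seed Mandatory integer seed.
#' @return A list with `panel` (an [aligned_panel()]) and `truth`: a
#'   list with `within_variable` (per-group planted variable columns),
#'   `windows` (tibble `start`, `end`, `diff_cols` list column) and
#'   `seed`.
#' @export
generate_panel <- function(ref_length = 2000L, n_target_a = 6L,
                           n_target_b = 4L, n_nontarget = 5L,
                           within_rate = 0.002, between_rate = 0.05,
                           n_diagnostic_windows = 2L, window_len = 25L,
                           diffs_per_window = 3L, window_starts = NULL,
                           seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(within_rate >= 0, within_rate < 0.5,
            between_rate >= 0, between_rate < 0.5,
            n_target_a >= 1, ref_length >= 100)
  set.seed(as.integer(seed))

  ref <- sample(c("A", "C", "G", "T"), ref_length, replace = TRUE)

  # windows: fixed or evenly spread, non-overlapping
  if (n_diagnostic_windows > 0L) {
    if (is.null(window_starts)) {
      slot <- ref_length %/% (n_diagnostic_windows + 1L)
      if (slot <= window_len) {
        stop("alignment too short for the requested diagnostic windows",
             call. = FALSE)
      }
      window_starts <- slot * seq_len(n_diagnostic_windows) -
        window_len %/% 2L
    }
    stopifnot(length(window_starts) == n_diagnostic_windows,
              all(window_starts >= 1),
              all(window_starts + window_len - 1L <= ref_length))
    win_cols <- unlist(lapply(window_starts, function(s) {
      s:(s + window_len - 1L)
    }))
    if (anyDuplicated(win_cols)) {
      stop("diagnostic windows must not overlap", call. = FALSE)
    }
  } else {
    window_starts <- integer(0)
    win_cols <- integer(0)
  }
  free_cols <- setdiff(seq_len(ref_length), win_cols)

  mutate_cols <- function(seq_chars, cols) {
    seq_chars[cols] <- rand_base_not(seq_chars[cols])
    seq_chars
  }

  n_between <- round(between_rate * ref_length)
  if (n_between > length(free_cols)) {
    stop("between_rate leaves no room outside the diagnostic windows",
         call. = FALSE)
  }

  # species bases: group A sits on the reference; group B and each
  # non-target diverge independently at between_rate
  base_a <- ref
  base_b <- if (n_target_b > 0L) {
    mutate_cols(ref, sample(free_cols, n_between))
  } else {
    NULL
  }
  nt_bases <- lapply(seq_len(n_nontarget), function(i) {
    mutate_cols(ref, sample(free_cols, n_between))
  })

  # within-group variable sites: distinct columns, each mutated in
  # exactly one member, so the truth count is exact
  n_within <- round(within_rate * ref_length)
  plant_within <- function(members, pool) {
    if (n_within == 0L || length(members) < 2L) {
      return(list(members = members, cols = integer(0)))
    }
    cols <- sort(sample(pool, n_within))
    who <- sample(seq_along(members), n_within, replace = TRUE)
    for (k in seq_along(cols)) {
      m <- who[k]
      members[[m]][cols[k]] <- rand_base_not(members[[m]][cols[k]])
    }
    list(members = members, cols = cols)
  }

  group_a <- replicate(n_target_a, base_a, simplify = FALSE)
  pa <- plant_within(group_a, free_cols)
  group_a <- pa$members
  group_b <- list()
  pb <- list(cols = integer(0))
  if (n_target_b > 0L) {
    group_b <- replicate(n_target_b, base_b, simplify = FALSE)
    pb <- plant_within(group_b, free_cols)
    group_b <- pb$members
  }
  nt_seqs <- nt_bases

  # diagnostic windows for group A: inside each window, A members equal
  # the reference; every non-A sequence differs at the same
  # diffs_per_window columns (and at no A-variable column, since window
  # columns were excluded from all pools above)
  windows <- tibble::tibble(start = integer(0), end = integer(0),
                            diff_cols = list())
  if (n_diagnostic_windows > 0L) {
    diff_cols_list <- lapply(window_starts, function(s) {
      sort(sample(s:(s + window_len - 1L), diffs_per_window))
    })
    for (w in seq_along(window_starts)) {
      for (col in diff_cols_list[[w]]) {
        alt <- ALT_BASE[[ref[col]]]
        group_b <- lapply(group_b, function(x) { x[col] <- alt; x })
        nt_seqs <- lapply(nt_seqs, function(x) { x[col] <- alt; x })
      }
    }
    windows <- tibble::tibble(
      start = as.integer(window_starts),
      end = as.integer(window_starts + window_len - 1L),
      diff_cols = diff_cols_list
    )
  }

  seqs <- c(
    stats::setNames(vapply(group_a, paste, character(1), collapse = ""),
                    sprintf("A%02d", seq_len(n_target_a))),
    if (n_target_b > 0L) {
      stats::setNames(vapply(group_b, paste, character(1), collapse = ""),
                      sprintf("B%02d", seq_len(n_target_b)))
    },
    stats::setNames(vapply(nt_seqs, paste, character(1), collapse = ""),
                    sprintf("NT%d", seq_len(n_nontarget)))
  )
  groups <- c(
    rep("A", n_target_a),
    rep("B", if (n_target_b > 0L) n_target_b else 0L),
    sprintf("NT%d", seq_len(n_nontarget))
  )
  names(groups) <- names(seqs)

  list(
    panel = aligned_panel(seqs, groups),
    truth = list(
      within_variable = list(A = pa$cols, B = pb$cols),
      windows = windows,
      seed = as.integer(seed)
    )
  )
}

#' Simulate a qPCR run
#'
#' Cq values follow the standard-curve model
#' `Cq = slope * log10(copies) + intercept + Normal(0, cq_sd)`; each
#' well amplifies with probability `p_detect` (dropout models the
#' stochastic loss of detection at low template copy numbers), and
#' non-amplifying wells get NA Cq (written as `no-amp` on disk).
#'
#' @param wells Data frame with columns `sample`, `marker`, `copies`
#'   and optional `dilution` and `p_detect` (default 1).
#' @param slope,intercept Curve parameters (defaults -3.3219 and 38:
#'   100% efficiency, single-copy detection just inside a 40-cycle
#'   run).
#' @param cq_sd Replicate noise SD in cycles (default 0).
#' @param n_replicates Replicates per well row (default 4, the field
#'   protocol).
#' @param seed Mandatory integer seed.
#' @return Replicate tibble (`sample`, `marker`, `replicate`, `cq`,
#'   plus `dilution`/`copies` carried through).
#' @export
generate_qpcr_run <- function(wells, slope = -3.3219, intercept = 38,
                              cq_sd = 0, n_replicates = 4L, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(cq_sd >= 0)
  wells <- tibble::as_tibble(wells)
  if (!"p_detect" %in% names(wells)) wells$p_detect <- 1
  stopifnot(all(wells$p_detect >= 0 & wells$p_detect <= 1),
            all(wells$copies > 0))
  set.seed(as.integer(seed))

  out <- tidyr::expand_grid(i = seq_len(nrow(wells)),
                            replicate = seq_len(n_replicates))
  w <- wells[out$i, ]
  n <- nrow(out)
  cq <- slope * log10(w$copies) + intercept + stats::rnorm(n, 0, cq_sd)
  detected <- stats::runif(n) <= w$p_detect
  cq[!detected] <- NA_real_
  res <- tibble::tibble(
    sample = w$sample, marker = w$marker,
    replicate = out$replicate, cq = cq
  )
  if ("dilution" %in% names(w)) res$dilution <- w$dilution
  res$copies <- w$copies
  res
}
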