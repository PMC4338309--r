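# Plasmid-standard copy numbers and qPCR standard curves.
#
# Copy number of a plasmid standard from its mass: a double-stranded
# base pair weighs 650 Daltons (g/mol), so a plasmid of `total_length`
# bp has molar mass total_length * 650 g/mol and
#   copies = mass[g] / (total_length * 650) * N_A,  N_A = 6.022e23.
# No end-group correction is applied; this reproduces the standard
# bench arithmetic rather than refining the chemistry.
#
# A standard curve is the least-squares fit of Cq on log10(copies);
# amplification efficiency = 10^(-1/slope) - 1, so a slope of
# -log2(10) ~ -3.3219 cycles/decade corresponds to 100% efficiency
# (perfect doubling each cycle).

AVOGADRO <- 6.022e23
DALTONS_PER_BP <- 650

#' Plasmid copies from DNA mass
#'
#' @param total_length Combined plasmid + insert length in bp.
#' @param mass_ng DNA mass in nanograms.
#' @return Estimated number of molecules (vectorized; linear in mass,
#'   inverse-linear in length).
#' @export
#' @examples
#' copies_from_mass(3000, 1)  # ~3.09e8 molecules
copies_from_mass <- function(total_length, mass_ng) {
  if (any(total_length <= 0)) stop("total_length must be positive", call. = FALSE)
  if (any(mass_ng < 0)) stop("mass_ng must be non-negative", call. = FALSE)
  mass_ng * 1e-9 / (total_length * DALTONS_PER_BP) * AVOGADRO
}

#' Fit a qPCR standard curve
#'
#' Least-squares regression of Cq on log10(copies). Replicate wells at
#' the same dilution enter as individual points (variance is
#' preserved, not averaged away).
#'
#' @param data Data frame of standard-dilution wells.
#' @param copies,cq Columns holding template copies and Cq (unquoted;
#'   defaults `copies`, `cq`). Wells with NA Cq (no amplification) are
#'   dropped.
#' @return An object of class `standard_curve` with elements `slope`
#'   (cycles per decade), `intercept` (cycles), `r2` (squared Pearson
#'   correlation), `efficiency` (fraction; 1 = 100%), `n`, `fit` (the
#'   underlying `lm`) and `data`.
#' @export
#' @examples
#' d <- data.frame(copies = 10^(1:5), cq = -3.3219 * (1:5) + 40)
#' fit_standard_curve(d)
fit_standard_curve <- function(data, copies = copies, cq = cq) {
  copies <- rlang::eval_tidy(rlang::enquo(copies), data)
  cq <- rlang::eval_tidy(rlang::enquo(cq), data)
  keep <- !is.na(cq)
  copies <- copies[keep]; cq <- cq[keep]
  if (any(copies <= 0)) stop("copies must be positive", call. = FALSE)
  if (length(unique(copies)) < 3L) {
    stop("standard curve needs at least 3 points with distinct copy numbers",
         call. = FALSE)
  }
  df <- tibble::tibble(log10_copies = log10(copies), cq = cq)
  fit <- stats::lm(cq ~ log10_copies, data = df)
  slope <- unname(stats::coef(fit)[["log10_copies"]])
  intercept <- unname(stats::coef(fit)[["(Intercept)"]])
  r2 <- stats::cor(df$log10_copies, df$cq)^2
  structure(
    list(
      slope = slope, intercept = intercept, r2 = r2,
      efficiency = 10^(-1 / slope) - 1,
      n = nrow(df), fit = fit, data = df
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve> Cq = ", format(x$slope, digits = 5),
      " * log10(copies) + ", format(x$intercept, digits = 5), "\n",
      "R2 = ", format(x$r2, digits = 4),
      ", efficiency = ", format(100 * x$efficiency, digits = 4),
      "%, n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Tidy a standard curve
#'
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @return Coefficient-level tibble (term, estimate, std.error,
#'   statistic, p.value).
#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"]
  )
}

#' One-row summary of a standard curve
#'
#' @param x A `standard_curve`.
#' @param ... Unused.
#' @return Tibble with `slope`, `intercept`, `r2`, `efficiency`, `n`.
#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, r2 = x$r2,
    efficiency = x$efficiency, n = x$n
  )
}

#' Copy number from Cq via a standard curve
#'
#' Inverts the curve: `copies = 10^((cq - intercept) / slope)`.
#'
#' @param cq Numeric vector of Cq values (NA propagates).
#' @param curve A `standard_curve`.
#' @return Estimated copies per reaction.
#' @export
copies_from_cq <- function(cq, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((cq - curve$intercept) / curve$slope)
}

#' Compare single-assay and multiplex Cq values
#'
#' Joins two (marker, dilution, Cq) tables — one from assays run alone,
#' one from the same assays multiplexed in a shared reaction — and
#' reports the per-condition Cq shift. Keys missing from one table are
#' carried with NA (absent, not an error).
#'
#' @param single,multiplex Data frames with columns `marker`,
#'   `dilution`, `cq`.
#' @return Tibble with `marker`, `dilution`, `cq_single`,
#'   `cq_multiplex`, `delta` (`cq_multiplex - cq_single`); the maximum
#'   absolute shift is available via `attr(, "max_abs_delta")`.
#' @export
compare_single_multiplex <- function(single, multiplex) {
  s <- dplyr::select(tibble::as_tibble(single), "marker", "dilution",
                     cq_single = "cq")
  m <- dplyr::select(tibble::as_tibble(multiplex), "marker", "dilution",
                     cq_multiplex = "cq")
  out <- dplyr::full_join(s, m, by = c("marker", "dilution"))
  out$delta <- out$cq_multiplex - out$cq_single
  attr(out, "max_abs_delta") <- if (all(is.na(out$delta))) NA_real_ else
    max(abs(out$delta), na.rm = TRUE)
  out
}

#' Plot a standard curve
#'
#' Standard-dilution wells with the fitted Cq ~ log10(copies) line and
#' the slope/R2/efficiency annotation.
#'
#' @param object A `standard_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  lab <- sprintf("slope = %.3f   R² = %.3f   eff = %.0f%%",
                 object$slope, object$r2, 100 * object$efficiency)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$log10_copies, y = .data$cq)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "log10(template copies)", y = "Cq",
      title = "qPCR standard curve", subtitle = lab
    )
}
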