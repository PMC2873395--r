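# PCR amplification efficiency from a standard (dilution) curve.

#' Fit a qPCR standard curve and compute amplification efficiency
#'
#' Ordinary least squares of Cq on log10 template input. Efficiency is
#' obtained from the slope by `E = (10^(-1/slope) - 1) x 100`; a perfectly
#' doubling reaction has slope `-1/log10(2) ~= -3.32` and E = 100%. The
#' amplification factor is `1 + E/100`.
#'
#' @param series a [make_dilution_series()] result, or a data.frame with
#'   columns `log10_input` and `cq`.
#' @return An `efficiency_fit`: list with `assay_id`, `slope`, `intercept`,
#'   `r_squared`, `efficiency_percent`, `amplification_factor`.
#' @export
fit_standard_curve <- function(series) {
  if (inherits(series, "dilution_series")) {
    pts <- series$points
    assay_id <- series$assay_id
  } else {
    pts <- as.data.frame(series)
    assay_id <- attr(series, "assay_id") %||% NA_character_
  }
  stopifnot(all(c("log10_input", "cq") %in% names(pts)))
  if (nrow(pts) < 3)
    stop("a dilution series needs at least 3 points", call. = FALSE)
  if (length(unique(pts$log10_input)) < 2)
    stop("log10_input values must not all be equal", call. = FALSE)
  fit <- stats::lm(cq ~ log10_input, data = pts)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("no amplification signal: slope of Cq on log10 input is not negative",
         call. = FALSE)
  eff <- (10^(-1 / slope) - 1) * 100
  structure(list(assay_id = assay_id, slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 efficiency_percent = eff,
                 amplification_factor = 1 + eff / 100),
            class = "efficiency_fit")
}

#' @export
print.efficiency_fit <- function(x, ...) {
  cat(sprintf("<efficiency_fit> %s: slope %.4f, E = %.1f%% (AF %.3f), R2 %.4f\n",
              x$assay_id, x$slope, x$efficiency_percent,
              x$amplification_factor, x$r_squared))
  invisible(x)
}
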