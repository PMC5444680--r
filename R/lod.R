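#' Fit a through-origin concentration profile
#'
#' The branch distance obeys `e^rho - 1 = (c_mut/c_wt) * exp(-ddG/RT)`: a
#' line through the origin in the relative mutant abundance, with slope
#' `exp(-ddG/RT)` carrying the physico-chemical impact of the mismatch.
#' This fits that line by least squares (optionally weighted), so that a
#' full dilution series or a single measurement point both determine the
#' profile; with one point the slope is exactly `(e^rho - 1)/(c_mut/c_wt)`.
#'
#' @param fraction Relative mutant fractions of the measurements.
#' @param rho Branch distances measured at those fractions.
#' @param fraction_of Whether `fraction` is `c_mut/c_wt` (the natural
#'   abscissa of the profile, default) or `c_mut/c_total` (the dilution
#'   table convention); the latter is converted via `x = f/(1-f)`.
#' @param weights Optional non-negative weights (e.g. inverse variances)
#'   for heteroscedastic multi-point series; unweighted by default.
#' @param thermo [thermo_config()] used to express the slope as an implied
#'   ddG.
#' @return Object of class `conc_profile`: `x`, `y = e^rho - 1`, `slope`,
#'   `fitted`, `residuals`, `r_squared` (through-origin), `ddG` (implied,
#'   kcal/mol), `thermo`.
#' @examples
#' pr <- fit_profile(c(0.01, 0.04, 0.10), log1p(c(0.01, 0.04, 0.10) * 25),
#'                   fraction_of = "wt")
#' coef(pr)  # slope 25
#' @export
fit_profile <- function(fraction, rho, fraction_of = c("wt", "total"),
                        weights = NULL, thermo = thermo_config()) {
  fraction_of <- match.arg(fraction_of)
  if (length(fraction) != length(rho))
    stop("fraction and rho lengths differ")
  keep <- fraction > 0
  if (!any(keep)) stop("at least one point with positive fraction required")
  # a (0, rho=0) point carries no information for a through-origin fit
  fraction <- fraction[keep]; rho <- rho[keep]
  if (!is.null(weights)) weights <- weights[keep]
  x <- if (fraction_of == "total") fraction / (1 - fraction) else fraction
  y <- expm1(rho)
  w <- if (is.null(weights)) rep(1, length(x)) else {
    if (any(weights < 0)) stop("weights must be non-negative")
    weights
  }
  slope <- sum(w * x * y) / sum(w * x^2)
  fitted <- slope * x
  res <- y - fitted
  r2 <- if (length(x) > 1) 1 - sum(w * res^2) / sum(w * y^2) else NA_real_
  structure(list(x = x, y = y, weights = w, slope = slope, fitted = fitted,
                 residuals = res, r_squared = r2,
                 ddG = -thermo$RT * log(slope), thermo = thermo),
            class = "conc_profile")
}

#' @export
coef.conc_profile <- function(object, ...) c(slope = object$slope)

#' Predicted branch distance at a given mutant fraction
#' @param object A `conc_profile`.
#' @param fraction Relative mutant fractions.
#' @param fraction_of See [fit_profile()].
#' @param ... Unused.
#' @return Predicted rho values.
#' @export
predict.conc_profile <- function(object, fraction,
                                 fraction_of = c("wt", "total"), ...) {
  fraction_of <- match.arg(fraction_of)
  x <- if (fraction_of == "total") fraction / (1 - fraction) else fraction
  log1p(object$slope * x)
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf(paste0("<conc_profile> %d point(s), slope exp(-ddG/RT) = %.3f",
                     " (implied ddG = %.3f kcal/mol)\n"),
              length(x$x), x$slope, x$ddG))
  if (!is.na(x$r_squared))
    cat(sprintf("  through-origin R^2 = %.4f\n", x$r_squared))
  invisible(x)
}

#' @export
plot.conc_profile <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "c_mut / c_wt",
                 ylab = expression(e^rho - 1), pch = 16,
                 xlim = c(0, max(x$x) * 1.05), ylim = c(0, max(x$y) * 1.05),
                 ...)
  graphics::abline(0, x$slope, lty = 2)
  invisible(x)
}

#' Convert a rho threshold into a concentration detection limit
#'
#' Inverts the through-origin profile at the detection threshold:
#' `c_limit = (e^(rho_t) - 1)/slope` in `c_mut/c_wt` units, also expressed
#' as `c_mut/c_total = c_limit/(1 + c_limit)`. The default threshold
#' `rho_t = 0.5` is an empirical calibration of the platform noise floor,
#' not a universal constant; supply your own for other noise regimes.
#'
#' @param profile A [fit_profile()] result (or a positive slope).
#' @param rho_t Detection threshold on the branch distance (default 0.5).
#' @return Object of class `detection_limit` with `rho_t`, `slope`,
#'   `c_mut_over_c_wt`, `c_mut_over_c_total`.
#' @export
detection_limit <- function(profile, rho_t = 0.5) {
  slope <- if (inherits(profile, "conc_profile")) profile$slope
           else as.numeric(profile)
  if (!is.finite(slope) || slope <= 0) stop("slope must be positive")
  if (rho_t < 0) stop("rho_t must be non-negative")
  c_wt <- expm1(rho_t) / slope
  structure(list(rho_t = rho_t, slope = slope, c_mut_over_c_wt = c_wt,
                 c_mut_over_c_total = c_wt / (1 + c_wt)),
            class = "detection_limit")
}

#' @export
print.detection_limit <- function(x, ...) {
  cat(sprintf(paste0("<detection_limit> rho_t = %.3g, slope = %.3f\n",
                     "  c_mut/c_wt = %.4g   c_mut/c_total = %.4g (%.2f%%)\n"),
              x$rho_t, x$slope, x$c_mut_over_c_wt, x$c_mut_over_c_total,
              100 * x$c_mut_over_c_total))
  invisible(x)
}

#' Panel-wide detection limits from single measurements
#'
#' Because the concentration profile is linear through the origin, a single
#' measurement of rho at a known fraction determines each mutation's
#' profile; this derives one detection limit per panel mutation and flags
#' the weakest one (smallest slope, largest limit).
#'
#' @param labels Mutation labels.
#' @param fractions Relative mutant fraction of each measurement.
#' @param rhos Measured branch distances.
#' @param rho_t Detection threshold.
#' @param fraction_of See [fit_profile()].
#' @param thermo [thermo_config()].
#' @return Data frame of class `panel_lod`: per mutation `label`, `slope`,
#'   `ddG`, `lod_wt` (`c_mut/c_wt`), `lod_total` (`c_mut/c_total`),
#'   `weakest`; attributes `weakest` (label) and `lod_below_1pct` (is the
#'   weakest mutation's `lod_total` below 1%?).
#' @export
panel_lod <- function(labels, fractions, rhos, rho_t = 0.5,
                      fraction_of = c("total", "wt"),
                      thermo = thermo_config()) {
  fraction_of <- match.arg(fraction_of)
  stopifnot(length(labels) == length(fractions),
            length(labels) == length(rhos))
  if (any(fractions <= 0)) stop("all measurement fractions must be positive")
  rows <- lapply(seq_along(labels), function(i) {
    pr <- fit_profile(fractions[i], rhos[i], fraction_of = fraction_of,
                      thermo = thermo)
    dl <- detection_limit(pr, rho_t)
    data.frame(label = labels[i], slope = pr$slope, ddG = pr$ddG,
               lod_wt = dl$c_mut_over_c_wt,
               lod_total = dl$c_mut_over_c_total, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$weakest <- out$slope == min(out$slope)
  structure(out, weakest = out$label[which.min(out$slope)],
            lod_below_1pct = max(out$lod_total) < 0.01,
            rho_t = rho_t, class = c("panel_lod", "data.frame"))
}

#' @export
print.panel_lod <- function(x, ...) {
  cat(sprintf("<panel_lod> %d mutations, rho_t = %.3g\n", nrow(x),
              attr(x, "rho_t")))
  print.data.frame(x, digits = 4)
  cat(sprintf("  weakest mutation: %s%s\n", attr(x, "weakest"),
              if (attr(x, "lod_below_1pct"))
                " (panel LOD < 1% relative concentration)" else ""))
  invisible(x)
}
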