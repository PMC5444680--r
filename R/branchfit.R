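#' Build the test-versus-reference scatter
#'
#' Joins a test (mixture) and a reference (pure wild type) intensity table
#' on `probe_id`, drops probes that fall below the background threshold in
#' either channel, and stores natural-log intensities. Because the branch
#' statistic is a log-ratio, the device-dependent optical factor A cancels
#' between channels and no cross-array normalization is performed.
#'
#' @param reference,test Intensity tables (data frames with `probe_id` and
#'   `intensity`; [simulate_array()] output or [read_intensity_table()]).
#' @param background_threshold Intensity floor applied to both channels.
#'   `NULL` (default) uses each table's `below_background` flags when
#'   present, else 0.
#' @return Data frame of class `scatter_data`: `probe_id`, `i_ref`,
#'   `i_test`, `log_ref`, `log_test`, `retained`; attribute `n_dropped`.
#' @export
build_scatter <- function(reference, test, background_threshold = NULL) {
  need <- c("probe_id", "intensity")
  if (!all(need %in% names(reference)) || !all(need %in% names(test)))
    stop("intensity tables need columns probe_id and intensity")
  m <- merge(reference[c("probe_id", "intensity",
                         intersect("below_background", names(reference)))],
             test[c("probe_id", "intensity",
                    intersect("below_background", names(test)))],
             by = "probe_id", suffixes = c("_ref", "_test"))
  if (nrow(m) == 0) stop("reference and test share no probe_ids")
  if (is.null(background_threshold)) {
    below <- rep(FALSE, nrow(m))
    if ("below_background_ref" %in% names(m))
      below <- below | m$below_background_ref
    if ("below_background_test" %in% names(m))
      below <- below | m$below_background_test
    retained <- !below & m$intensity_ref > 0 & m$intensity_test > 0
  } else {
    retained <- m$intensity_ref > background_threshold &
      m$intensity_test > background_threshold
  }
  out <- data.frame(probe_id = m$probe_id,
                    i_ref = m$intensity_ref, i_test = m$intensity_test,
                    log_ref = ifelse(retained, log(m$intensity_ref), NA_real_),
                    log_test = ifelse(retained, log(m$intensity_test), NA_real_),
                    retained = retained, stringsAsFactors = FALSE)
  structure(out, n_dropped = sum(!retained),
            class = c("scatter_data", "data.frame"))
}

#' Fit the LOWESS reference line
#'
#' Robust locally weighted scatterplot smoothing of `log_test` on `log_ref`
#' over all retained probes. The robustifying iterations downweight the
#' minority of elevated mutation/side-branch points so the fitted curve
#' tracks the reference branch; an isotonic post-pass enforces a monotone
#' non-decreasing curve. Fitting in natural-log space makes the vertical
#' distance to the curve directly the branch statistic rho.
#'
#' @param scatter A [build_scatter()] result.
#' @param span LOWESS smoother span (fraction of points; default 0.5).
#' @param iters Number of robustifying iterations (default 3).
#' @return Object of class `reference_line` (an evaluable curve).
#' @export
fit_reference_line <- function(scatter, span = 0.5, iters = 3L) {
  stopifnot(inherits(scatter, "scatter_data"))
  s <- scatter[scatter$retained, ]
  if (nrow(s) < 10) stop("need at least 10 retained points to fit the reference line")
  lw <- stats::lowess(s$log_ref, s$log_test, f = span, iter = iters)
  iso <- stats::isoreg(lw$x, lw$y)
  structure(list(x = lw$x, y = iso$yf, span = span, iters = iters),
            class = "reference_line")
}

#' Evaluate the reference line
#'
#' Linear interpolation within the fitted range; constant extrapolation
#' from the nearest fitted point outside it.
#'
#' @param object A `reference_line`.
#' @param newx Log reference intensities at which to evaluate.
#' @param ... Unused.
#' @return Expected `log_test` values.
#' @export
predict.reference_line <- function(object, newx, ...) {
  if (length(unique(object$x)) < 2)
    return(rep(object$y[1], length(newx)))
  stats::approx(object$x, object$y, xout = newx, rule = 2, ties = mean)$y
}

#' @export
print.reference_line <- function(x, ...) {
  cat(sprintf("<reference_line> LOWESS span %.2f, %d robust iterations, %d points, x in [%.2f, %.2f]\n",
              x$span, x$iters, length(x$x), min(x$x), max(x$x)))
  invisible(x)
}

#' Branch distances and the branch statistic rho
#'
#' For one candidate mutation, computes every retained probe's vertical
#' distance to the reference line, `d = log I_test - line(log I_ref)`,
#' labels each probe `mutation`, `side` or `reference` according to
#' [probes_for_hypothesis()], and summarizes the mutation branch by
#' `rho = median(d over the mutation set)` — a dimensionless, natural-log
#' scale quantity in which the optical factor A has cancelled.
#'
#' @param scatter A [build_scatter()] result.
#' @param line A [fit_reference_line()] result.
#' @param probeset The probeset shared by both arrays.
#' @param h One hypothesis row.
#' @return Data frame of class `branch_result` (`probe_id`, `log_ref`,
#'   `distance`, `branch`) with attributes `rho`, `hypothesis`,
#'   `n_mutation`, `n_side`, `n_reference`. `rho` is `NA` when no mutation
#'   set probe survived filtering.
#' @export
branch_distances <- function(scatter, line, probeset, h) {
  stopifnot(inherits(scatter, "scatter_data"),
            inherits(line, "reference_line"))
  h <- .as_hypothesis_row(h)
  sets <- probes_for_hypothesis(probeset, h)
  s <- scatter[scatter$retained, ]
  d <- s$log_test - predict(line, s$log_ref)
  branch <- rep("reference", nrow(s))
  branch[s$probe_id %in% sets$mutation$probe_id] <- "mutation"
  branch[s$probe_id %in% sets$side$probe_id] <- "side"
  rho <- if (any(branch == "mutation"))
    stats::median(d[branch == "mutation"]) else NA_real_
  structure(data.frame(probe_id = s$probe_id, log_ref = s$log_ref,
                       distance = d, branch = branch,
                       stringsAsFactors = FALSE),
            rho = rho, hypothesis = h$label,
            n_mutation = sum(branch == "mutation"),
            n_side = sum(branch == "side"),
            n_reference = sum(branch == "reference"),
            class = c("branch_result", "data.frame"))
}
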