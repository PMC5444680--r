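#' One-sided Wilcoxon rank-sum test in log space
#'
#' Tests whether `x` is stochastically greater than `y`. For tie-free
#' samples small enough that the exact null distribution is cheap
#' (`n1 * n2 <= 2500`) the exact tail of the Mann-Whitney statistic is
#' used; otherwise the normal approximation with continuity and mid-rank
#' tie correction. The log p-value is computed
#' directly on the log scale (`pwilcox`/`pnorm` with `log.p = TRUE`) so
#' that p' = -ln(p) remains finite and accurate for extremely significant
#' results where p itself underflows.
#'
#' @param x Distances of the mutation set.
#' @param y Distances of the reference pool.
#' @return List with `p`, `log_p`, `p_prime = -log_p`, the Mann-Whitney
#'   statistic `W` and the `method` used.
#' @export
ranksum_greater <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  exact <- n1 * n2 <= 2500 && !any(ties > 1)
  if (exact) {
    log_p <- stats::pwilcox(W - 1, n1, n2, lower.tail = FALSE, log.p = TRUE)
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {  # all observations tied
      log_p <- 0
    } else {
      z <- (W - mu - 0.5) / sqrt(sigma2)
      log_p <- stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
    }
    method <- "normal"
  }
  log_p <- min(log_p, 0)
  list(p = exp(log_p), log_p = log_p, p_prime = -log_p, W = W,
       method = method)
}

#' Test one mutation hypothesis against the reference branch
#'
#' One-sided rank-sum test of the mutation-set distances being
#' stochastically greater than the reference-branch distances (all retained
#' probes with no mismatch at the hypothesis position). Side-branch probes
#' share the position but not the base and take part in neither sample.
#'
#' @param branches A [branch_distances()] result.
#' @param alpha Significance level (default 0.01).
#' @param min_mutation,min_reference Minimum retained probes required in
#'   each pool; below these the result is flagged and carries no p-value.
#' @return One-row data frame: `label`, `rho`, `p`, `p_prime`,
#'   `n_mutation`, `n_reference`, `significant`, `note`.
#' @export
test_hypothesis <- function(branches, alpha = 0.01, min_mutation = 2L,
                            min_reference = 10L) {
  stopifnot(inherits(branches, "branch_result"))
  d_mut <- branches$distance[branches$branch == "mutation"]
  d_ref <- branches$distance[branches$branch == "reference"]
  out <- data.frame(label = attr(branches, "hypothesis"),
                    rho = attr(branches, "rho"),
                    p = NA_real_, p_prime = NA_real_,
                    n_mutation = length(d_mut), n_reference = length(d_ref),
                    significant = FALSE, note = "", stringsAsFactors = FALSE)
  if (length(d_mut) < min_mutation || length(d_ref) < min_reference) {
    out$note <- "insufficient retained probes"
    return(out)
  }
  ts <- ranksum_greater(d_mut, d_ref)
  out$p <- ts$p
  out$p_prime <- ts$p_prime
  out$significant <- ts$p < alpha
  out
}

#' Call the mutation status of a sample
#'
#' The central fit of the package: given a wild-type reference array and a
#' test array over the same probeset, builds the log-log scatter, fits the
#' robust LOWESS reference line once, and for every candidate mutation
#' computes the branch distance rho and the rank-sum p-value. The sample is
#' called as the most significant hypothesis (largest p') if it reaches
#' `alpha`, otherwise as wild type. Panel mutations are assumed mutually
#' exclusive; if several distinct positions reach significance a warning is
#' raised and the best hypothesis is still reported.
#'
#' @param reference,test Intensity tables (reference = pure wild type).
#' @param probeset The [design_probeset()] the arrays were measured on.
#' @param hypotheses A `mutation_hypotheses` data frame
#'   ([enumerate_hypotheses()]).
#' @param alpha Per-hypothesis significance level (default 0.01).
#' @param bonferroni If `TRUE`, divide `alpha` by the number of hypotheses.
#'   Off by default.
#' @param span,iters LOWESS parameters, see [fit_reference_line()].
#' @param background_threshold See [build_scatter()].
#' @return Object of class `hyb_call`: list with `results` (one row per
#'   hypothesis: rho, p, p', significance), `call` (label or
#'   `"wild type"`), `gap` (p' of best minus second best), `scatter`,
#'   `line`, `alpha`.
#' @examples
#' \donttest{
#' ps <- design_probeset(kras_target())
#' hyp <- kras_hypotheses()
#' cfg <- sim_config()
#' wt <- sample_spec(list(kras_target()), 10)
#' mix <- mixture_spec(kras_target(),
#'                     apply_mutation(kras_target(), 13, "G"), 0.05, 10)
#' ref <- simulate_array(ps, wt, cfg, seed = 1)
#' tst <- simulate_array(ps, mix, cfg, seed = 2)
#' fit <- hyb_call(ref, tst, ps, hyp)
#' fit$call  # "10C>G"
#' }
#' @export
hyb_call <- function(reference, test, probeset, hypotheses, alpha = 0.01,
                     bonferroni = FALSE, span = 0.5, iters = 3L,
                     background_threshold = NULL) {
  stopifnot(inherits(probeset, "probeset"), is.data.frame(hypotheses),
            nrow(hypotheses) > 0)
  if (bonferroni) alpha <- alpha / nrow(hypotheses)
  scatter <- build_scatter(reference, test, background_threshold)
  line <- fit_reference_line(scatter, span = span, iters = iters)
  results <- do.call(rbind, lapply(seq_len(nrow(hypotheses)), function(i) {
    br <- branch_distances(scatter, line, probeset,
                           hypotheses[i, , drop = FALSE])
    cbind(test_hypothesis(br, alpha = alpha),
          position = hypotheses$position[i],
          alias = hypotheses$alias[i], stringsAsFactors = FALSE)
  }))
  rownames(results) <- NULL
  sig <- which(results$significant)
  called <- if (length(sig)) {
    best <- sig[which.max(results$p_prime[sig])]
    if (length(unique(results$position[sig])) > 1)
      warning("multiple positions significant; panel mutations are assumed ",
              "mutually exclusive - reporting the most significant hypothesis")
    results$label[best]
  } else "wild type"
  ord <- order(results$p_prime, decreasing = TRUE)
  gap <- if (nrow(results) >= 2 && !anyNA(results$p_prime[ord[1:2]]))
    results$p_prime[ord[1]] - results$p_prime[ord[2]] else NA_real_
  structure(list(results = results, call = called, gap = gap,
                 scatter = scatter, line = line, alpha = alpha),
            class = "hyb_call")
}

#' @export
print.hyb_call <- function(x, ...) {
  cat(sprintf("<hyb_call> %d hypotheses, alpha = %g\n  call: %s\n",
              nrow(x$results), x$alpha, x$call))
  if (!is.na(x$gap)) cat(sprintf("  p' gap to runner-up: %.2f\n", x$gap))
  invisible(x)
}

#' @export
summary.hyb_call <- function(object, ...) {
  r <- object$results[order(object$results$p_prime, decreasing = TRUE), ]
  cat(sprintf("Mutation call: %s (alpha = %g)\n\n", object$call,
              object$alpha))
  print(data.frame(label = r$label, alias = r$alias,
                   rho = round(r$rho, 4), p_prime = round(r$p_prime, 2),
                   p = signif(r$p, 3), significant = r$significant,
                   row.names = NULL))
  invisible(object)
}

#' @export
as.data.frame.hyb_call <- function(x, ...) x$results

#' Scatter plot of a mutation call
#'
#' Log-log test-versus-reference intensity scatter with the fitted
#' reference line, highlighting the mutation and side branches of the
#' called (or a chosen) hypothesis.
#'
#' @param x A [hyb_call()] object.
#' @param hypothesis Label to highlight; defaults to the called mutation
#'   (or the most significant hypothesis for a wild-type call).
#' @param probeset The probeset used for the call (needed to recover the
#'   branch membership).
#' @param hypotheses The hypothesis panel used for the call.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hyb_call <- function(x, probeset, hypotheses, hypothesis = NULL, ...) {
  if (is.null(hypothesis))
    hypothesis <- if (x$call != "wild type") x$call else
      x$results$label[which.max(x$results$p_prime)]
  h <- hypotheses[hypotheses$label == hypothesis, , drop = FALSE]
  br <- branch_distances(x$scatter, x$line, probeset, h)
  s <- x$scatter[x$scatter$retained, ]
  col <- c(reference = "grey30", side = "dodgerblue3", mutation = "firebrick")
  pch <- c(reference = 1, side = 2, mutation = 15)
  graphics::plot(s$log_ref, s$log_test,
                 col = col[br$branch], pch = pch[br$branch],
                 xlab = "ln I (reference)", ylab = "ln I (test)",
                 main = sprintf("branch scatter: %s (rho = %.2f)",
                                hypothesis, attr(br, "rho")), ...)
  graphics::lines(x$line$x, x$line$y, lwd = 2)
  graphics::legend("topleft", bty = "n",
                   legend = c("reference", "side", "mutation", "reference line"),
                   col = c(col, "black"), pch = c(pch, NA),
                   lty = c(NA, NA, NA, 1))
  invisible(x)
}

#' Write a call report as JSON
#'
#' @param x A [hyb_call()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_call_json <- function(x, path) {
  stopifnot(inherits(x, "hyb_call"))
  jsonlite::write_json(
    list(call = x$call, alpha = x$alpha, gap = x$gap,
         hypotheses = x$results[, c("label", "alias", "rho", "p", "p_prime",
                                    "n_mutation", "n_reference",
                                    "significant", "note")]),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
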