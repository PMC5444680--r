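# shared fixtures, built once per test run

kras_ps <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- design_probeset(kras_target())
    cache
  }
})

kras_hyp <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- kras_hypotheses()
    cache
  }
})

noise_free_config <- function(...) {
  sim_config(noise_cv = 0, background_mean = 0, background_sd = 0,
             background_threshold = 0, ...)
}

# pure wild-type sample at a given total concentration
wt_spec <- function(c_total = 10) sample_spec(list(kras_target()), c_total)

# wt/mutant mixture for one hypothesis row, fraction = c_mut/c_total
mix_spec <- function(h, fraction, c_total = 10) {
  wt <- kras_target()
  mixture_spec(wt, apply_mutation(wt, h$position, h$alt_base),
               fraction, c_total)
}

# reference/test pair -> branch result for one hypothesis
branch_fit <- function(reference, test, h, probeset = kras_ps(), ...) {
  sc <- build_scatter(reference, test, ...)
  ln <- fit_reference_line(sc)
  branch_distances(sc, ln, probeset, h)
}

# measured rho at each step of a simulated dilution series
series_rhos <- function(series, h, probeset = kras_ps()) {
  vapply(series$samples, function(s)
    attr(branch_fit(series$reference, s$table, h, probeset), "rho"),
    numeric(1))
}

# penalty of the wild-type mismatch carried by the mutation branch of h:
# target wt base opposite the probe base complementary to the alternative
branch_penalty <- function(h, penalties = default_penalty_table()) {
  probe_base <- chartr("ACGT", "TGCA", h$alt_base)
  penalties$ddG[penalties$target_base == h$wt_base &
                  penalties$probe_base == probe_base]
}

# exhaustive-enumeration oracle for the one-sided rank-sum tail
# (tie-free data; every rank assignment equally likely under the null)
brute_ranksum_p <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  ws <- colSums(matrix(seq_len(n)[combs], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(ws >= w_obs)
}
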