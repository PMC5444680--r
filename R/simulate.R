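#' Simulation configuration
#'
#' Parameters of the synthetic microarray generator: the device-dependent
#' optical proportionality factor `A` (fluorescence units per nM of bound
#' target in the linear Langmuir regime), the perfect-match baseline free
#' energy, the mismatch penalty table, the thermodynamic scale, the number
#' of replicate spots per probe, the multiplicative lognormal spot noise
#' (coefficient of variation), and the additive residual background of the
#' background-subtracted scanner output.
#'
#' Defaults: `A = 1e4` a.u./nM so a 5 nM pure wild-type sample puts the PM
#' probe near 5e4 a.u.; 8 replicate spots aggregated by their median;
#' `noise_cv = 0.15`. The generator emulates background-subtracted scanner
#' output, so the default additive background is zero-mean residual noise
#' (`background_mean = 0`, `background_sd = 4`) with a reliability floor
#' `background_threshold = max(2*background_mean, 5*background_sd)` below
#' which a probe's log-scale signal is flagged as unusable. A positive
#' `background_mean` models platforms without background subtraction; note
#' that an un-subtracted additive floor compresses the log-distances of dim
#' probes, so pair it with a proportionally higher threshold. The median of
#' the lognormal noise is 1, so the per-probe median is an unbiased
#' estimate of the expected intensity.
#'
#' @param A Optical proportionality factor (> 0).
#' @param dG_pm Perfect-match baseline free energy (kcal/mol).
#' @param penalties Mismatch penalty table.
#' @param thermo [thermo_config()].
#' @param n_replicates Replicate spots per probe (>= 1).
#' @param noise_cv Lognormal multiplicative noise CV (>= 0).
#' @param background_mean,background_sd Additive Gaussian background (a.u.).
#' @param background_threshold Intensity floor below which a probe's
#'   aggregated signal is flagged.
#' @param saturating If `TRUE`, use the saturating Langmuir isotherm
#'   `I = A z/(1+z)` with `z = sum_s c_s exp(-dG_s/RT)` instead of the
#'   default linear regime. Off by default: the analysis framework assumes
#'   the linear form.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(A = 1e4, dG_pm = 0,
                       penalties = default_penalty_table(),
                       thermo = thermo_config(),
                       n_replicates = 8L, noise_cv = 0.15,
                       background_mean = 0, background_sd = 4,
                       background_threshold = max(2 * background_mean,
                                                  5 * background_sd),
                       saturating = FALSE) {
  if (A <= 0) stop("A must be positive")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (noise_cv < 0 || background_mean < 0 || background_sd < 0)
    stop("noise parameters must be non-negative")
  structure(list(A = A, dG_pm = dG_pm,
                 penalties = validate_penalty_table(penalties),
                 thermo = thermo, n_replicates = as.integer(n_replicates),
                 noise_cv = noise_cv, background_mean = background_mean,
                 background_sd = background_sd,
                 background_threshold = background_threshold,
                 saturating = isTRUE(saturating)),
            class = "sim_config")
}

#' Sample specification: species and concentrations
#'
#' @param species Named character vector of target-strand sequences
#'   (names are species labels), or a `target_sequence` list.
#' @param conc_nM Concentrations in nM, one per species, all >= 0.
#' @return Object of class `sample_spec`: data frame with columns `name`,
#'   `bases`, `conc_nM`; attribute `c_total`.
#' @export
sample_spec <- function(species, conc_nM) {
  if (is.list(species))
    species <- stats::setNames(
      vapply(species, function(s) as_target(s)$bases, character(1)),
      vapply(species, function(s) as_target(s)$name, character(1)))
  if (length(species) != length(conc_nM))
    stop("one concentration per species required")
  if (any(conc_nM < 0)) stop("concentrations must be >= 0")
  out <- data.frame(name = names(species), bases = unname(species),
                    conc_nM = as.numeric(conc_nM), stringsAsFactors = FALSE)
  structure(out, c_total = sum(conc_nM),
            class = c("sample_spec", "data.frame"))
}

#' Two-species wild-type/mutant mixture at fixed total concentration
#'
#' @param wt,mut Wild-type and mutant targets.
#' @param fraction Relative mutant abundance.
#' @param c_total Total ssDNA concentration (nM).
#' @param fraction_of Whether `fraction` means `c_mut/c_total` (default, the
#'   dilution-table convention) or `c_mut/c_wt`.
#' @return A [sample_spec()]; a pure wild-type sample when `fraction = 0`.
#' @export
mixture_spec <- function(wt, mut, fraction, c_total = 5,
                         fraction_of = c("total", "wt")) {
  fraction_of <- match.arg(fraction_of)
  if (fraction < 0 || fraction >= 1) stop("fraction must lie in [0, 1)")
  f_tot <- if (fraction_of == "total") fraction else fraction / (1 + fraction)
  wt <- as_target(wt); mut <- as_target(mut)
  spec <- sample_spec(
    stats::setNames(c(wt$bases, mut$bases), c(wt$name, mut$name)),
    c((1 - f_tot) * c_total, f_tot * c_total))
  attr(spec, "fraction_total") <- f_tot
  spec
}

# per-probe free energies against one species, vectorized over the probeset
.duplex_dg_vec <- function(probeset, species_bases, config) {
  tb <- strsplit(species_bases, "")[[1]]
  comp_t <- .comp(tb)
  pen <- config$penalties
  key <- paste0(pen$target_base, pen$probe_base)
  if ("position" %in% names(pen))
    stop("position-dependent penalty tables require duplex_delta_g(); the vectorized simulator supports position-independent tables")
  lut <- stats::setNames(pen$ddG, key)
  aligned <- t(vapply(strsplit(probeset$probes$bases, "", fixed = TRUE),
                      rev, character(nchar(species_bases))))
  n <- nrow(aligned)
  tmat <- matrix(tb, n, length(tb), byrow = TRUE)
  cmat <- matrix(comp_t, n, length(tb), byrow = TRUE)
  mism <- aligned != cmat
  pens <- matrix(0, n, length(tb))
  if (any(mism)) {
    k <- paste0(tmat[mism], aligned[mism])
    v <- lut[k]
    if (anyNA(v))
      stop("no penalty entry for mismatch context ",
           paste(unique(k[is.na(v)]), collapse = ", "))
    pens[mism] <- v
  }
  config$dG_pm + rowSums(pens)
}

#' Expected probe intensities under competitive Langmuir hybridization
#'
#' In the linear regime each species contributes independently:
#' `I = A * sum_s c_s * exp(-dG(probe, s)/RT)`. With a single species this
#' is the plain Langmuir wild-type intensity; with a wild-type/mutant
#' mixture it is the two-term competitive form whose ratio to the
#' reference intensity yields the branch distance rho.
#'
#' @param probeset A [design_probeset()] result.
#' @param sample A [sample_spec()].
#' @param config A [sim_config()].
#' @return Named numeric vector of expected intensities, one per probe.
#' @export
expected_intensity <- function(probeset, sample, config = sim_config()) {
  stopifnot(inherits(probeset, "probeset"), inherits(sample, "sample_spec"))
  L <- nchar(probeset$target$bases)
  if (any(nchar(sample$bases) != L))
    stop("species length differs from probe length")
  z <- 0
  for (i in seq_len(nrow(sample))) {
    dg <- .duplex_dg_vec(probeset, sample$bases[i], config)
    z <- z + sample$conc_nM[i] * exp(-dg / config$thermo$RT)
  }
  out <- if (config$saturating) config$A * z / (1 + z) else config$A * z
  stats::setNames(out, probeset$probes$probe_id)
}

#' Simulate one hybridization (an intensity table)
#'
#' Draws `n_replicates` spot intensities per probe,
#' `I_rep = expected * LogNormal(0, sigma) + N(bg_mean, bg_sd)` truncated at
#' zero, with `sigma` derived from `noise_cv`, and aggregates replicates by
#' their median — the same summary a scanner pipeline applies to technical
#' replicate spots. Rows whose median falls below `background_threshold`
#' are flagged (`below_background`), not removed; filtering happens
#' downstream in [build_scatter()].
#'
#' @inheritParams expected_intensity
#' @param seed Integer seed; the simulation is fully reproducible from it
#'   (R's default Mersenne-Twister RNG).
#' @return Data frame of class `intensity_table` with columns `probe_id`,
#'   `intensity`, `n_replicates`, `below_background`; attributes `sample`
#'   (species summary) and `seed`.
#' @export
simulate_array <- function(probeset, sample, config = sim_config(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expected <- expected_intensity(probeset, sample, config)
  n <- length(expected)
  r <- config$n_replicates
  sdlog <- sqrt(log1p(config$noise_cv^2))
  noise <- if (config$noise_cv > 0)
    matrix(stats::rlnorm(n * r, meanlog = 0, sdlog = sdlog), r, n)
  else matrix(1, r, n)
  bg <- if (config$background_mean > 0 || config$background_sd > 0)
    matrix(stats::rnorm(n * r, config$background_mean, config$background_sd),
           r, n)
  else matrix(0, r, n)
  draws <- pmax(rep(expected, each = r) * noise + bg, 0)
  med <- apply(draws, 2, stats::median)
  out <- data.frame(probe_id = names(expected), intensity = unname(med),
                    n_replicates = r,
                    below_background = unname(med < config$background_threshold),
                    stringsAsFactors = FALSE)
  structure(out, sample = as.data.frame(sample)[, c("name", "conc_nM")],
            seed = seed, class = c("intensity_table", "data.frame"))
}

#' Simulate a dilution series of one mutation
#'
#' Generates mixtures at relative mutant fractions
#' `f_k = start_fraction / dilution_factor^(k-1)`, `k = 1..n_steps`, at
#' constant total concentration, plus a pure wild-type reference array.
#' Fractions follow the dilution-table convention `c_mut/c_total`.
#'
#' @inheritParams simulate_array
#' @param h One hypothesis row (the spiked-in mutation).
#' @param start_fraction Largest relative mutant fraction, in (0, 1).
#' @param dilution_factor Factor between consecutive steps (> 1).
#' @param n_steps Number of mixtures.
#' @param c_total Total ssDNA concentration (nM).
#' @param seed Base seed; step k uses `seed + k`, the reference `seed`.
#' @return List with `reference` (intensity table), `samples` (list of
#'   `list(fraction, spec, table)`) and `fractions`.
#' @export
make_dilution_series <- function(probeset, h, start_fraction = 0.10,
                                 dilution_factor = 2.5, n_steps = 6L,
                                 c_total = 5, config = sim_config(),
                                 seed = 1L) {
  h <- .as_hypothesis_row(h)
  if (start_fraction <= 0 || start_fraction > 1)
    stop("start_fraction must lie in (0, 1]")
  if (dilution_factor <= 1 && n_steps > 1)
    stop("dilution_factor must exceed 1")
  fractions <- start_fraction / dilution_factor^(seq_len(n_steps) - 1)
  wt <- probeset$target
  mut <- apply_mutation(wt, h$position, h$alt_base)
  ref_spec <- sample_spec(stats::setNames(wt$bases, wt$name), c_total)
  reference <- simulate_array(probeset, ref_spec, config, seed = seed)
  samples <- lapply(seq_along(fractions), function(k) {
    spec <- mixture_spec(wt, mut, fractions[k], c_total, "total")
    list(fraction = fractions[k], spec = spec,
         table = simulate_array(probeset, spec, config,
                                seed = as.integer(seed) + k))
  })
  list(reference = reference, samples = samples, fractions = fractions,
       hypothesis = h$label)
}
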