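#' Thermodynamic configuration
#'
#' Temperature and gas constant defining the RT scale used everywhere free
#' energies enter an exponent. Defaults to the 65 degC hybridization
#' temperature (338.15 K), giving RT ~ 0.672 kcal/mol.
#'
#' @param temperature Absolute temperature in kelvin.
#' @param R Ideal gas constant in kcal/(mol K).
#' @return Object of class `thermo_config` with elements `temperature`,
#'   `R` and the derived `RT` (kcal/mol).
#' @export
thermo_config <- function(temperature = 338.15, R = 1.987e-3) {
  if (temperature <= 0) stop("temperature must be positive (kelvin)")
  structure(list(temperature = temperature, R = R, RT = R * temperature),
            class = "thermo_config")
}

#' @export
print.thermo_config <- function(x, ...) {
  cat(sprintf("<thermo_config> T = %.2f K, RT = %.4f kcal/mol\n",
              x$temperature, x$RT))
  invisible(x)
}

#' Mismatch free-energy penalty table
#'
#' `default_penalty_table()` returns the position-independent per-mismatch
#' penalties ddG (kcal/mol) used by the simulator and the examples: one row
#' per non-Watson-Crick (target base, probe base) pairing, values in the
#' 1.4-2.8 kcal/mol range typical of nearest-neighbor duplex thermodynamics,
#' with wobble-like G.T/T.G pairings weakest. A mismatch never strengthens a
#' duplex, so all entries are non-negative; a Watson-Crick pairing carries
#' penalty 0 by construction and has no row. An optional `position` column
#' (NA = any position) allows position-dependent tables behind the same
#' interface.
#'
#' All inference in the package treats ddG as an unknown estimated from
#' data; this table only parameterizes synthetic data.
#'
#' @return Data frame with columns `target_base`, `probe_base`, `ddG`.
#' @export
default_penalty_table <- function() {
  tab <- data.frame(
    target_base = c("A", "A", "A", "C", "C", "C",
                    "G", "G", "G", "T", "T", "T"),
    probe_base  = c("A", "C", "G", "A", "C", "T",
                    "A", "G", "T", "C", "G", "T"),
    ddG = c(2.4, 2.8, 2.0, 2.6, 2.2, 1.8,
            2.0, 1.6, 1.4, 2.8, 1.4, 2.2),
    stringsAsFactors = FALSE)
  validate_penalty_table(tab)
}

validate_penalty_table <- function(tab) {
  need <- c("target_base", "probe_base", "ddG")
  if (!all(need %in% names(tab)))
    stop("penalty table needs columns: ", paste(need, collapse = ", "))
  if (any(tab$ddG < 0))
    stop("mismatch penalties must be non-negative (a mismatch never strengthens the duplex)")
  comp <- .comp(tab$target_base)
  if (any(comp == tab$probe_base))
    stop("penalty table contains a Watson-Crick pairing; the PM entry is implicitly 0")
  tab
}

#' Read / write a penalty table as TSV
#' @param path File path.
#' @param tab Penalty table data frame.
#' @return `read_penalty_table()` the validated table; `write_penalty_table()`
#'   the path, invisibly.
#' @export
read_penalty_table <- function(path) {
  validate_penalty_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_penalty_table
#' @export
write_penalty_table <- function(tab, path) {
  utils::write.table(validate_penalty_table(tab), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# per-position penalty lookup; errors on a missing mismatch context
.penalty_for <- function(tab, target_base, probe_base, position) {
  hit <- tab$target_base == target_base & tab$probe_base == probe_base
  if ("position" %in% names(tab)) {
    pos_hit <- hit & !is.na(tab$position) & tab$position == position
    if (any(pos_hit)) hit <- pos_hit else hit <- hit & is.na(tab$position)
  }
  if (!any(hit))
    stop(sprintf("no penalty entry for mismatch context %s.%s at position %d",
                 target_base, probe_base, position))
  tab$ddG[which(hit)[1]]
}

# mismatch scan of a probe (5'->3') against a target (5'->3'):
# returns data.frame(position, target_base, probe_base) of non-WC pairings
.mismatch_scan <- function(probe_bases, target_bases) {
  if (nchar(probe_bases) != nchar(target_bases))
    stop("probe and target lengths differ")
  tb <- strsplit(target_bases, "")[[1]]
  pb <- rev(strsplit(probe_bases, "")[[1]])  # aligned 3'->5' along target
  mism <- which(pb != .comp(tb))
  data.frame(position = mism, target_base = tb[mism], probe_base = pb[mism],
             stringsAsFactors = FALSE)
}

.probe_bases <- function(probe) {
  if (is.character(probe)) return(probe[1])
  if (is.data.frame(probe)) {
    if (nrow(probe) != 1L) stop("expected a single probe")
    return(probe$bases)
  }
  stop("probe must be a character sequence or one probeset row")
}

#' Duplex free energy under the additive mismatch model
#'
#' Computes the free energy of a probe-target duplex as a perfect-match
#' baseline plus one penalty per position at which the probe base does not
#' Watson-Crick pair the target base. The baseline is shared by all probes
#' (first-order model: sequence-composition differences are absorbed into
#' the optical factor A), so only the mismatch penalties carry sequence
#' information.
#'
#' @param probe Probe sequence 5'->3' (character) or one row of
#'   `probeset$probes`.
#' @param target [target_sequence()] or character scalar (the species the
#'   probe hybridizes with, wild type or mutant).
#' @param dG_pm Perfect-match baseline free energy (kcal/mol).
#' @param penalties Penalty table, see [default_penalty_table()].
#' @return Duplex free energy in kcal/mol (numeric scalar).
#' @export
duplex_delta_g <- function(probe, target, dG_pm = 0,
                           penalties = default_penalty_table()) {
  target <- as_target(target)
  mism <- .mismatch_scan(.probe_bases(probe), target$bases)
  pen <- if (nrow(mism) == 0) 0 else
    sum(vapply(seq_len(nrow(mism)), function(i)
      .penalty_for(penalties, mism$target_base[i], mism$probe_base[i],
                   mism$position[i]), numeric(1)))
  dG_pm + pen
}

#' Mismatch penalty difference ddG between two target species
#'
#' Returns `dG(probe, mut) - dG(probe, wt)`. For a probe in the mutation
#' branch of a hypothesis this equals minus the penalty of its wild-type
#' mismatch and is identical across all probes of that branch under the
#' additive model; for reference-branch probes it is the (positive) penalty
#' the mutant incurs at the substituted position.
#'
#' @inheritParams duplex_delta_g
#' @param wt,mut Wild-type and mutant target species.
#' @return ddG in kcal/mol.
#' @export
delta_delta_g <- function(probe, wt, mut,
                          penalties = default_penalty_table()) {
  duplex_delta_g(probe, mut, 0, penalties) -
    duplex_delta_g(probe, wt, 0, penalties)
}
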