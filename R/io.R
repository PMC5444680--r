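#' Write / read an intensity table
#'
#' The package's single TSV intensity dialect: columns `probe_id`,
#' `intensity`, and optionally `n_replicates` and `below_background`;
#' `#key=value` header lines carry sample metadata. The same format is the
#' ingestion point for real array data — map a vendor export's per-probe
#' aggregated, background-subtracted signals into these columns.
#'
#' @param tbl An intensity table data frame.
#' @param path File path.
#' @return `write_intensity_table()` returns `path` invisibly;
#'   `read_intensity_table()` a validated `intensity_table` data frame
#'   with the parsed metadata in attribute `meta`.
#' @export
write_intensity_table <- function(tbl, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- attr(tbl, "sample")
  if (!is.null(meta))
    writeLines(sprintf("#species=%s:%g", meta$name, meta$conc_nM), con)
  if (!is.null(attr(tbl, "seed")))
    writeLines(paste0("#seed=", attr(tbl, "seed")), con)
  utils::write.table(as.data.frame(tbl), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_intensity_table
#' @export
read_intensity_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty intensity table: ", path)
  is_meta <- cumprod(startsWith(lines, "#")) == 1
  meta <- sub("^#", "", lines[is_meta])
  body <- lines[!is_meta]
  tbl <- utils::read.delim(text = body, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "intensity") %in% names(tbl)))
    stop("intensity table ", path,
         " must have columns probe_id and intensity")
  if (is.character(tbl$intensity)) {
    num <- suppressWarnings(as.numeric(tbl$intensity))
    if (anyNA(num))
      stop("non-numeric intensity at line(s) ",
           paste(which(is.na(num)) + sum(is_meta) + 1, collapse = ", "),
           " of ", path)
    tbl$intensity <- num
  }
  if (anyNA(tbl$intensity))
    stop("missing intensity at line(s) ",
         paste(which(is.na(tbl$intensity)) + sum(is_meta) + 1,
               collapse = ", "), " of ", path)
  dup <- unique(tbl$probe_id[duplicated(tbl$probe_id)])
  if (length(dup))
    stop("duplicated probe_id(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  structure(tbl, meta = meta, class = c("intensity_table", "data.frame"))
}

#' Generate the three validation experiment sets
#'
#' Writes synthetic analogues of the three study designs to `outdir`:
#' * **set1** — a six-step dilution series of mutation `10C>G` (factor 2.5
#'   from 10% down to 0.10% `c_mut/c_total`) at 5 nM total, plus its pure
#'   wild-type reference;
#' * **set2** — the 12 panel mutations each at 5% relative concentration
#'   and a wild-type negative control, at 10 nM total;
#' * **set3** — 7 clinical-like samples: elevated spot noise
#'   (`noise_cv = 0.25`, emulating degraded FFPE-derived DNA) and
#'   uniformly random unknown mutant fractions in 5-40%, mutations drawn
#'   from the panel, at 10 nM total.
#'
#' Alongside the intensity tables it writes the probeset (FASTA + TSV),
#' the penalty table, and `manifest.tsv` with the ground truth of every
#' sample for downstream assertions. Fully reproducible from `seed`.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param config Baseline [sim_config()]; set3 overrides its `noise_cv`.
#' @return The manifest data frame, invisibly.
#' @export
make_fixtures <- function(outdir, seed = 1L, config = sim_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  ps <- design_probeset(kras_target())
  hyp <- kras_hypotheses()
  write_probeset(ps, file.path(outdir, "probeset"))
  write_penalty_table(config$penalties, file.path(outdir, "penalties.tsv"))
  wt <- ps$target
  manifest <- list()
  path_of <- function(...) file.path(outdir, ...)
  rel <- function(p) sub(paste0("^", outdir, "/?"), "", p)

  # set 1: dilution series of 10C>G at 5 nM
  h10g <- hyp[hyp$label == "10C>G", ]
  ser <- make_dilution_series(ps, h10g, 0.10, 2.5, 6L, c_total = 5,
                              config = config, seed = seed)
  dir.create(path_of("set1"), showWarnings = FALSE)
  p_ref <- path_of("set1", "reference.tsv")
  write_intensity_table(ser$reference, p_ref)
  manifest[[1]] <- data.frame(set = "set1", sample_id = "set1_ref",
                              path = rel(p_ref), truth = "wild type",
                              fraction_total = 0, c_total = 5,
                              noise_cv = config$noise_cv,
                              stringsAsFactors = FALSE)
  for (k in seq_along(ser$samples)) {
    p <- path_of("set1", sprintf("dilution_%d.tsv", k))
    write_intensity_table(ser$samples[[k]]$table, p)
    manifest[[length(manifest) + 1]] <-
      data.frame(set = "set1", sample_id = sprintf("set1_f%d", k),
                 path = rel(p), truth = "10C>G",
                 fraction_total = ser$fractions[k], c_total = 5,
                 noise_cv = config$noise_cv, stringsAsFactors = FALSE)
  }

  # set 2: 12 mutants at 5% + wild-type control, 10 nM
  dir.create(path_of("set2"), showWarnings = FALSE)
  wt_spec <- sample_spec(list(wt), 10)
  p <- path_of("set2", "reference.tsv")
  write_intensity_table(simulate_array(ps, wt_spec, config,
                                       seed = seed + 100L), p)
  manifest[[length(manifest) + 1]] <-
    data.frame(set = "set2", sample_id = "set2_ref", path = rel(p),
               truth = "wild type", fraction_total = 0, c_total = 10,
               noise_cv = config$noise_cv, stringsAsFactors = FALSE)
  p <- path_of("set2", "wt_control.tsv")
  write_intensity_table(simulate_array(ps, wt_spec, config,
                                       seed = seed + 101L), p)
  manifest[[length(manifest) + 1]] <-
    data.frame(set = "set2", sample_id = "set2_wt", path = rel(p),
               truth = "wild type", fraction_total = 0, c_total = 10,
               noise_cv = config$noise_cv, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(hyp))) {
    h <- hyp[i, ]
    spec <- mixture_spec(wt, apply_mutation(wt, h$position, h$alt_base),
                         0.05, 10)
    p <- path_of("set2", sprintf("mut_%s.tsv", gsub(">", "to", h$label)))
    write_intensity_table(simulate_array(ps, spec, config,
                                         seed = seed + 110L + i), p)
    manifest[[length(manifest) + 1]] <-
      data.frame(set = "set2", sample_id = paste0("set2_", i),
                 path = rel(p), truth = h$label, fraction_total = 0.05,
                 c_total = 10, noise_cv = config$noise_cv,
                 stringsAsFactors = FALSE)
  }

  # set 3: 7 clinical-like samples, elevated noise, random fractions
  dir.create(path_of("set3"), showWarnings = FALSE)
  cfg3 <- config
  cfg3$noise_cv <- 0.25
  set.seed(seed + 200L)
  picks <- sample.int(nrow(hyp), 7, replace = TRUE)
  fracs <- stats::runif(7, 0.05, 0.40)
  p <- path_of("set3", "reference.tsv")
  write_intensity_table(simulate_array(ps, wt_spec, cfg3,
                                       seed = seed + 201L), p)
  manifest[[length(manifest) + 1]] <-
    data.frame(set = "set3", sample_id = "set3_ref", path = rel(p),
               truth = "wild type", fraction_total = 0, c_total = 10,
               noise_cv = cfg3$noise_cv, stringsAsFactors = FALSE)
  for (k in 1:7) {
    h <- hyp[picks[k], ]
    spec <- mixture_spec(wt, apply_mutation(wt, h$position, h$alt_base),
                         fracs[k], 10)
    p <- path_of("set3", sprintf("clinical_%d.tsv", k))
    write_intensity_table(simulate_array(ps, spec, cfg3,
                                         seed = seed + 210L + k), p)
    manifest[[length(manifest) + 1]] <-
      data.frame(set = "set3", sample_id = paste0("set3_", k),
                 path = rel(p), truth = h$label, fraction_total = fracs[k],
                 c_total = 10, noise_cv = cfg3$noise_cv,
                 stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, manifest)
  utils::write.table(manifest, path_of("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Load an analysis run configuration
#'
#' YAML configuration with the file paths and parameters of a pipeline run.
#' Values in `overrides` (e.g. parsed command-line flags) take precedence
#' over the file, which takes precedence over the documented defaults.
#'
#' @param path YAML file, or `NULL` for defaults only.
#' @param overrides Named list of overriding values.
#' @return Named list of validated parameters.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(probeset = NULL, penalties = NULL, reference = NULL,
                   test = NULL, span = 0.5, iters = 3L, alpha = 0.01,
                   rho_t = 0.5, background_threshold = NULL, seed = 1L,
                   outdir = ".")
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    file_cfg <- yaml::read_yaml(path)
    cfg[names(file_cfg)] <- file_cfg
  }
  cfg[names(overrides)] <- overrides
  for (key in c("probeset", "penalties", "reference", "test")) {
    p <- cfg[[key]]
    if (!is.null(p)) {
      probe_file <- if (key == "probeset") paste0(p, ".tsv") else p
      if (!file.exists(probe_file))
        stop("configured ", key, " file not found: ", probe_file)
    }
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (cfg$span <= 0 || cfg$span > 1) stop("span must lie in (0, 1]")
  cfg
}
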