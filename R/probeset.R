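#' @keywords internal
.BASES <- c("A", "C", "G", "T")

.comp <- function(x) chartr("ACGT", "TGCA", x)

.rev_string <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

.revcomp <- function(x) .rev_string(.comp(x))

#' Wild-type target sequence
#'
#' Light container for the single-stranded target region a probeset is
#' designed against. Coordinates throughout the package are 1-based indices
#' into this sequence, read 5' to 3'.
#'
#' @param bases Character scalar over the alphabet `A`, `C`, `G`, `T`.
#'   Must be at least 7 nt long so that at least one interior mismatch
#'   position exists.
#' @param name Identifier for the target.
#' @return An object of class `target_sequence` with elements `bases` and
#'   `name`.
#' @examples
#' target_sequence("ACGTACGTACGT", "toy")
#' @export
target_sequence <- function(bases, name = "target") {
  bases <- toupper(as.character(bases)[1])
  if (is.na(bases) || nchar(bases) < 7)
    stop("target sequence must be at least 7 nt long")
  if (grepl("[^ACGT]", bases))
    stop("target sequence alphabet must be exactly {A,C,G,T}")
  structure(list(bases = bases, name = as.character(name)[1]),
            class = "target_sequence")
}

as_target <- function(x, name = "target") {
  if (inherits(x, "target_sequence")) x else target_sequence(x, name)
}

#' @export
print.target_sequence <- function(x, ...) {
  cat(sprintf("<target_sequence> %s (%d nt)\n  5'-%s-3'\n",
              x$name, nchar(x$bases), x$bases))
  invisible(x)
}

#' KRAS exon 2 wild-type target
#'
#' The 23-nt wild-type target region around KRAS codons 12 and 13, on the
#' strand that carries the hotspot cytosines. Its reverse complement is the
#' commonly quoted 5'-GTTGGAGCTGGTGGCGTAGGCAA-3' sequence.
#'
#' @return A [target_sequence()].
#' @export
kras_target <- function() {
  target_sequence("TTGCCTACGCCACCAGCTCCAAC", "KRAS_exon2_wt")
}

#' Substitute a point mutation into a target
#'
#' @param target A [target_sequence()] or character scalar.
#' @param position 1-based index into the target.
#' @param alt_base Replacement base; must differ from the wild-type base.
#' @return A new `target_sequence` carrying the substitution.
#' @export
apply_mutation <- function(target, position, alt_base) {
  target <- as_target(target)
  position <- as.integer(position)
  if (position < 1 || position > nchar(target$bases))
    stop("position outside target")
  wt <- substr(target$bases, position, position)
  if (identical(wt, alt_base))
    stop("alt_base equals the wild-type base at position ", position)
  if (!alt_base %in% .BASES) stop("alt_base must be one of A,C,G,T")
  b <- target$bases
  substr(b, position, position) <- alt_base
  target_sequence(b, paste0(target$name, "_", position, wt, ">", alt_base))
}

.mutate_string <- function(bases, positions, variants) {
  for (k in seq_along(positions))
    substr(bases, positions[k], positions[k]) <- variants[k]
  bases
}

#' Design a PM/1MM/2MM mismatch probeset
#'
#' Constructs the full probeset against a wild-type target: the unique
#' perfect-match (PM) probe, every single-mismatch (1MM) probe at interior
#' positions (3 variant bases per eligible position), and every
#' double-mismatch (2MM) probe whose two mismatch positions are separated by
#' at least `min_separation` nt. Mismatches within `edge_margin` nt of either
#' end of the duplex are excluded, because a mismatch near the helix boundary
#' or two interacting mismatches would carry an extra, non-additive free
#' energy penalty.
#'
#' Probe sequences are stored 5' to 3' (i.e. the reverse complement of the
#' mutated target); mismatch annotations always refer to target coordinates,
#' with `variant` the target-strand base the probe pairs perfectly with.
#'
#' @param target [target_sequence()] or character scalar.
#' @param edge_margin Mismatches are excluded from the first/last this many
#'   positions (default 4 nt).
#' @param min_separation Minimum distance between the two mismatches of a
#'   2MM probe (default 5 nt).
#' @return Object of class `probeset`: a list with the `target`, the design
#'   parameters and `probes`, a data frame with columns `probe_id`, `bases`,
#'   `n_mismatch`, `pos1`, `var1`, `pos2`, `var2` (`NA` where absent).
#' @examples
#' ps <- design_probeset(kras_target())
#' nrow(ps$probes)  # 1 PM + 45 1MM + 495 2MM = 541
#' @export
design_probeset <- function(target, edge_margin = 4L, min_separation = 5L) {
  target <- as_target(target)
  edge_margin <- as.integer(edge_margin)
  min_separation <- as.integer(min_separation)
  if (edge_margin < 1L) stop("edge_margin must be >= 1")
  if (min_separation < 2L) stop("min_separation must be >= 2")
  L <- nchar(target$bases)
  if (L - 2L * edge_margin < 1L)
    stop("target too short: no interior position admits a mismatch")
  interior <- seq.int(edge_margin + 1L, L - edge_margin)
  wt <- strsplit(target$bases, "")[[1]]

  rows <- list(data.frame(probe_id = "PM", n_mismatch = 0L,
                          pos1 = NA_integer_, var1 = NA_character_,
                          pos2 = NA_integer_, var2 = NA_character_,
                          stringsAsFactors = FALSE))
  one <- expand.grid(pos1 = interior, var1 = .BASES,
                     stringsAsFactors = FALSE)
  one <- one[one$var1 != wt[one$pos1], , drop = FALSE]
  one <- one[order(one$pos1, one$var1), , drop = FALSE]
  rows[[2]] <- data.frame(
    probe_id = sprintf("m%02d%s", one$pos1, one$var1),
    n_mismatch = 1L, pos1 = one$pos1, var1 = one$var1,
    pos2 = NA_integer_, var2 = NA_character_, stringsAsFactors = FALSE)

  pairs <- expand.grid(pos1 = interior, pos2 = interior)
  pairs <- pairs[pairs$pos2 - pairs$pos1 >= min_separation, , drop = FALSE]
  if (nrow(pairs)) {
    two <- merge(
      merge(pairs, data.frame(var1 = .BASES)),
      data.frame(var2 = .BASES))
    two <- two[two$var1 != wt[two$pos1] & two$var2 != wt[two$pos2], ,
               drop = FALSE]
    two <- two[order(two$pos1, two$var1, two$pos2, two$var2), , drop = FALSE]
    rows[[3]] <- data.frame(
      probe_id = sprintf("m%02d%s.m%02d%s", two$pos1, two$var1,
                         two$pos2, two$var2),
      n_mismatch = 2L, pos1 = two$pos1, var1 = two$var1,
      pos2 = two$pos2, var2 = two$var2, stringsAsFactors = FALSE)
  }
  probes <- do.call(rbind, rows)
  rownames(probes) <- NULL

  mutated <- target$bases
  probes$bases <- vapply(seq_len(nrow(probes)), function(i) {
    b <- mutated
    if (!is.na(probes$pos1[i]))
      b <- .mutate_string(b, probes$pos1[i], probes$var1[i])
    if (!is.na(probes$pos2[i]))
      b <- .mutate_string(b, probes$pos2[i], probes$var2[i])
    .revcomp(b)
  }, character(1))
  if (anyDuplicated(probes$bases))
    stop("internal error: duplicate probes generated")
  probes <- probes[, c("probe_id", "bases", "n_mismatch",
                       "pos1", "var1", "pos2", "var2")]
  structure(list(target = target, probes = probes,
                 edge_margin = edge_margin, min_separation = min_separation),
            class = "probeset")
}

#' @export
print.probeset <- function(x, ...) {
  n <- table(factor(x$probes$n_mismatch, levels = 0:2))
  cat(sprintf(paste0(
    "<probeset> against %s (%d nt)\n",
    "  probes: %d PM, %d 1MM, %d 2MM (edge_margin=%d, min_separation=%d)\n"),
    x$target$name, nchar(x$target$bases), n[["0"]], n[["1"]], n[["2"]],
    x$edge_margin, x$min_separation))
  invisible(x)
}

#' Enumerate candidate point-mutation hypotheses
#'
#' For each position of interest, generates the three possible substitutions
#' of the wild-type base. Positions may be supplied in a user-facing counter
#' space that differs from raw target indices: with `label_offset = k` and
#' `label_reverse = TRUE` a supplied counter `p` refers to target index
#' `k - p` (counters running antiparallel to the stored strand, as in the
#' KRAS codon 12/13 panel); with `label_reverse = FALSE` it refers to index
#' `p - k`.
#'
#' @param target [target_sequence()] or character scalar.
#' @param positions Positions of interest, in label space.
#' @param label_offset,label_reverse Mapping from label space to target
#'   index (defaults: labels are target indices).
#' @param aliases Optional named character vector mapping nucleotide labels
#'   (e.g. `"10C>G"`) to alternative names (e.g. amino-acid notation
#'   `"G12A"`).
#' @return Data frame of class `mutation_hypotheses` with columns
#'   `label_position`, `position` (target index), `wt_base`, `alt_base`,
#'   `label`, `alias`; ordered by (label position, alternative base).
#' @examples
#' enumerate_hypotheses(kras_target(), c(9, 10, 12, 13),
#'                      label_offset = 23, label_reverse = TRUE)
#' @export
enumerate_hypotheses <- function(target, positions, label_offset = 0L,
                                 label_reverse = FALSE, aliases = NULL) {
  target <- as_target(target)
  if (length(positions) == 0)
    return(structure(
      data.frame(label_position = integer(), position = integer(),
                 wt_base = character(), alt_base = character(),
                 label = character(), alias = character(),
                 stringsAsFactors = FALSE),
      class = c("mutation_hypotheses", "data.frame")))
  positions <- as.integer(positions)
  idx <- if (label_reverse) as.integer(label_offset) - positions
         else positions - as.integer(label_offset)
  L <- nchar(target$bases)
  if (any(idx < 1L | idx > L))
    stop("position(s) outside target: ",
         paste(positions[idx < 1L | idx > L], collapse = ", "))
  wt <- strsplit(target$bases, "")[[1]]
  h <- do.call(rbind, lapply(order(positions), function(k) {
    alts <- sort(setdiff(.BASES, wt[idx[k]]))
    data.frame(label_position = positions[k], position = idx[k],
               wt_base = wt[idx[k]], alt_base = alts,
               stringsAsFactors = FALSE)
  }))
  h$label <- paste0(h$label_position, h$wt_base, ">", h$alt_base)
  h$alias <- if (is.null(aliases)) NA_character_ else
    unname(aliases[h$label])
  rownames(h) <- NULL
  structure(h, class = c("mutation_hypotheses", "data.frame"))
}

#' KRAS codon 12/13 hotspot mutation panel
#'
#' The 12 most commonly reported exon-2 KRAS point mutations: three
#' substitutions at each of the nucleotide counters 9, 10, 12 and 13, with
#' amino-acid aliases (e.g. `10C>G` = `G12A`). The counter-to-index mapping
#' is `index = 23 - counter` on the [kras_target()] strand.
#'
#' @return A `mutation_hypotheses` data frame of 12 rows.
#' @export
kras_hypotheses <- function() {
  enumerate_hypotheses(kras_target(), c(9L, 10L, 12L, 13L),
                       label_offset = 23L, label_reverse = TRUE,
                       aliases = kras_aliases())
}

#' @rdname kras_hypotheses
#' @export
kras_aliases <- function() {
  path <- system.file("extdata", "kras_aa_aliases.tsv",
                      package = "hybridsnv", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$amino_acid, tab$nucleotide)
}

.as_hypothesis_row <- function(h) {
  if (is.data.frame(h)) {
    if (nrow(h) != 1L) stop("expected exactly one hypothesis row")
    return(h)
  }
  stop("hypothesis must be a one-row 'mutation_hypotheses' data frame")
}

#' Probe subsets associated with a mutation hypothesis
#'
#' Splits the probes that carry a deliberate mismatch at the hypothesis
#' position into the *mutation set* (probes whose variant base at that
#' position equals the hypothesised alternative, i.e. probes that pair the
#' mutant perfectly there — 1MM and 2MM alike) and the *side set* (probes
#' mismatched at the position but with a different variant base). Probes
#' without a mismatch at the position form the reference branch and are not
#' returned here.
#'
#' @param probeset A [design_probeset()] result.
#' @param h One row of a `mutation_hypotheses` data frame.
#' @return List with data frames `mutation` and `side` (disjoint subsets of
#'   `probeset$probes`).
#' @export
probes_for_hypothesis <- function(probeset, h) {
  stopifnot(inherits(probeset, "probeset"))
  h <- .as_hypothesis_row(h)
  p <- probeset$probes
  at1 <- !is.na(p$pos1) & p$pos1 == h$position
  at2 <- !is.na(p$pos2) & p$pos2 == h$position
  if (!any(at1 | at2))
    stop("position ", h$position, " is not covered by any probe mismatch")
  hit <- (at1 & p$var1 == h$alt_base) | (at2 & p$var2 == h$alt_base)
  list(mutation = p[hit, , drop = FALSE],
       side = p[(at1 | at2) & !hit, , drop = FALSE])
}

#' Write / read a probeset
#'
#' `write_probeset()` writes `<prefix>.fasta` (probe sequences, headers
#' carrying `pos:wt>var` mismatch tokens) and a `<prefix>.tsv` sidecar with
#' the structured annotations plus `#`-prefixed metadata lines (target,
#' design parameters). `read_probeset()` reconstructs the probeset from the
#' pair and verifies that the annotations regenerate the FASTA sequences.
#'
#' @param probeset A `probeset`.
#' @param prefix Path prefix for the two files.
#' @return `write_probeset()` returns the two paths invisibly;
#'   `read_probeset()` returns a `probeset`.
#' @export
write_probeset <- function(probeset, prefix) {
  stopifnot(inherits(probeset, "probeset"))
  p <- probeset$probes
  wt <- strsplit(probeset$target$bases, "")[[1]]
  tok <- function(pos, var) ifelse(is.na(pos), "",
                                   paste0(pos, ":", wt[ifelse(is.na(pos), 1L, pos)], ">", var))
  ann <- trimws(paste(tok(p$pos1, p$var1), tok(p$pos2, p$var2)))
  headers <- trimws(paste(p$probe_id, ann))
  fasta <- paste0(prefix, ".fasta")
  tsv <- paste0(prefix, ".tsv")
  seqs <- Biostrings::DNAStringSet(stats::setNames(p$bases, headers))
  Biostrings::writeXStringSet(seqs, fasta)
  meta <- c(paste0("#target=", probeset$target$bases),
            paste0("#target_name=", probeset$target$name),
            paste0("#edge_margin=", probeset$edge_margin),
            paste0("#min_separation=", probeset$min_separation))
  con <- file(tsv, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(p, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, tsv = tsv))
}

#' @rdname write_probeset
#' @export
read_probeset <- function(prefix) {
  tsv <- paste0(prefix, ".tsv")
  fasta <- paste0(prefix, ".fasta")
  lines <- readLines(tsv, n = 50L)
  meta_n <- sum(cumprod(startsWith(lines, "#")))
  meta <- sub("^#", "", lines[seq_len(meta_n)])
  kv <- strsplit(meta, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  probes <- utils::read.delim(tsv, skip = meta_n, stringsAsFactors = FALSE,
                              colClasses = c(pos1 = "integer",
                                             pos2 = "integer",
                                             var1 = "character",
                                             var2 = "character"))
  ps <- structure(
    list(target = target_sequence(vals[["target"]], vals[["target_name"]]),
         probes = probes,
         edge_margin = as.integer(vals[["edge_margin"]]),
         min_separation = as.integer(vals[["min_separation"]])),
    class = "probeset")
  if (file.exists(fasta)) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    ids <- vapply(strsplit(names(seqs), " ", fixed = TRUE), `[`,
                  character(1), 1)
    m <- match(probes$probe_id, ids)
    if (anyNA(m) || !identical(unname(as.character(seqs)[m]), probes$bases))
      stop("probeset FASTA and TSV sidecar disagree")
  }
  ps
}
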