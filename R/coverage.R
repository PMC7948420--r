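#' Per-residue coverage across a multi-protease, multi-fragmentation design
#'
#' Locates each identified peptide in the protein (exact substring match; all
#' occurrences count) and computes, per residue, the number of distinct
#' experiments with at least one covering peptide, plus per-experiment and
#' combined coverage fractions. An experiment is one
#' (protease, fragmentation) combination; the survey design has eight.
#'
#' @param protein Protein sequence.
#' @param peptides data.frame with columns `peptide` and `experiment`.
#' @param protein_id Identifier stored on the profile.
#' @return Object of class `coverage_profile`: list with `protein_id`,
#'   `length`, `depth` (integer vector), `per_experiment_coverage` (named
#'   fractions), `combined_coverage` (fraction of residues with depth >= 1).
#' @export
map_peptides <- function(protein, peptides, protein_id = "protein") {
  stopifnot(is.character(protein), nzchar(protein))
  stopifnot(all(c("peptide", "experiment") %in% names(peptides)))
  n <- nchar(protein)
  experiments <- unique(as.character(peptides$experiment))
  covered <- matrix(FALSE, nrow = length(experiments), ncol = n,
                    dimnames = list(experiments, NULL))
  for (i in seq_len(nrow(peptides))) {
    pep <- peptides$peptide[i]
    hits <- gregexpr(pep, protein, fixed = TRUE)[[1]]
    if (hits[1] < 0) {
      stop("mapping error: peptide(s) not locatable in protein: ", pep)
    }
    for (s in hits) {
      covered[as.character(peptides$experiment[i]), s:(s + nchar(pep) - 1L)] <- TRUE
    }
  }
  depth <- if (length(experiments) == 0L) integer(n) else
    as.integer(colSums(covered))
  per_exp <- if (length(experiments) == 0L) numeric(0) else
    rowMeans(covered)
  structure(
    list(protein_id = protein_id, length = n, depth = depth,
         per_experiment_coverage = per_exp,
         combined_coverage = mean(depth >= 1L)),
    class = "coverage_profile"
  )
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %s: %d aa, combined coverage %.1f%% (%d experiments)\n",
              x$protein_id, x$length, 100 * x$combined_coverage,
              length(x$per_experiment_coverage)))
  invisible(x)
}

#' Tabulate a coverage profile for export
#'
#' @param profile A `coverage_profile`.
#' @return List with `summary` (one row per experiment plus a combined row;
#'   coverage as percent, 1 decimal) and `depth_track` (position, depth).
#' @export
coverage_tables <- function(profile) {
  stopifnot(inherits(profile, "coverage_profile"))
  summary <- data.frame(
    protein_id = profile$protein_id,
    experiment = c(names(profile$per_experiment_coverage), "combined"),
    coverage_pct = round(100 * c(profile$per_experiment_coverage,
                                 profile$combined_coverage), 1)
  )
  depth_track <- data.frame(position = seq_len(profile$length),
                            depth = profile$depth)
  list(summary = summary, depth_track = depth_track)
}
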