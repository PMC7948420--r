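#' Monoisotopic residue masses
#'
#' Masses of the 20 standard amino-acid residues (Da), i.e. the mass each
#' residue contributes inside a peptide chain (free amino acid minus water).
#'
#' @return Named numeric vector over the one-letter codes.
#' @export
amino_acid_masses <- function() {
  c(
    G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
    V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
    I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
    K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
    F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
  )
}

#' Mass constants
#'
#' Monoisotopic mass of water (added once per peptide) and of the proton
#' (added once per charge when converting neutral mass to m/z).
#'
#' @name mass_constants
#' @export
water_mass <- function() 18.0105646863

#' @rdname mass_constants
#' @export
proton_mass <- function() 1.007276467

#' Modification registry
#'
#' Reads the packaged table of modification monoisotopic mass shifts and the
#' residues (or termini) they target. A custom registry file with the same
#' three tab-separated columns (`name`, `delta_mass`, `targets`) may be
#' supplied; `targets` is a comma-separated set of one-letter residue codes
#' plus optionally `N-term` / `C-term`.
#'
#' @param path Path to a registry TSV; defaults to the packaged registry.
#' @return data.frame with columns `name`, `delta_mass`, `targets` (list
#'   column of character vectors).
#' @export
modification_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "modifications.tsv", package = "ptmforge")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("modification registry file not found: ", path)
  }
  reg <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "delta_mass", "targets") %in% names(reg)))
  if (!all(is.finite(reg$delta_mass))) stop("non-finite delta_mass in registry")
  reg$targets <- strsplit(reg$targets, ",", fixed = TRUE)
  reg
}

mod_delta <- function(name, registry = modification_registry()) {
  i <- match(name, registry$name)
  if (anyNA(i)) {
    stop("unknown modification(s): ", paste(name[is.na(i)], collapse = ", "))
  }
  registry$delta_mass[i]
}
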