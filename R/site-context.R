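#' Read a per-residue disorder track
#'
#' TSV with columns `position` and `score` (disorder propensity in `[0, 1]`),
#' e.g. parsed from DISOPRED-style output. Positions must be 1..L with no
#' gaps.
#'
#' @param path Path to the TSV.
#' @param threshold Score at/above which a residue is called disordered.
#' @return List of class `disorder_track`: `scores` (numeric), `threshold`.
#' @export
read_disorder_track <- function(path, threshold = 0.5) {
  tab <- utils::read.delim(path)
  disorder_track(tab$score[order(tab$position)], threshold)
}

#' @rdname read_disorder_track
#' @param scores Per-residue scores in order.
#' @export
disorder_track <- function(scores, threshold = 0.5) {
  scores <- as.numeric(scores)
  if (any(scores < 0 | scores > 1)) stop("disorder scores must be in [0, 1]")
  structure(list(scores = scores, threshold = threshold),
            class = "disorder_track")
}

#' Contextualize sites in a disorder track
#'
#' A residue (and any site on it) is called disordered when its score is at
#' or above the track threshold.
#'
#' @param sites data.frame with a `position` column (1-based).
#' @param track A [disorder_track()] for the same protein.
#' @return List: `sites` (input plus logical `disordered`), `tally`
#'   (`pct_disordered` of the protein, `n_sites_disordered`,
#'   `n_sites_ordered`).
#' @export
disorder_context <- function(sites, track) {
  stopifnot(inherits(track, "disorder_track"))
  if (nrow(sites) > 0L &&
      any(sites$position < 1L | sites$position > length(track$scores))) {
    stop("bounds error: site position outside disorder track")
  }
  dis <- track$scores >= track$threshold
  sites$disordered <- if (nrow(sites) > 0L) dis[sites$position] else logical()
  list(sites = sites,
       tally = data.frame(pct_disordered = 100 * mean(dis),
                          n_sites_disordered = sum(sites$disordered),
                          n_sites_ordered = sum(!sites$disordered)))
}

#' Read a domain interval table
#'
#' TSV with columns `protein_id`, `name`, `start`, `end`, `class` (one of
#' `catalytic`, `regulatory`, `interaction`). Coordinates are 1-based
#' inclusive; set `zero_based_half_open = TRUE` for BED-style input, which is
#' converted on read.
#'
#' @param path Path to the TSV.
#' @param zero_based_half_open Is the input BED-style 0-based half-open?
#' @return data.frame of 1-based inclusive intervals.
#' @export
read_domains <- function(path, zero_based_half_open = FALSE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (zero_based_half_open) {
    tab$start <- tab$start + 1L
  }
  if (any(tab$start > tab$end) || any(tab$start < 1L)) {
    stop("invalid domain intervals")
  }
  tab
}

#' Contextualize sites in domain intervals
#'
#' A site is in-domain when its position lies within any interval (both
#' endpoints inclusive).
#'
#' @param sites data.frame with `position` (and optionally `protein_id`,
#'   matched against the domain table when both carry it).
#' @param domains data.frame of intervals as from [read_domains()].
#' @return List: `sites` (input plus logical `in_domain` and `domain` name or
#'   NA), `fraction_in_domain`.
#' @export
domain_context <- function(sites, domains) {
  if (nrow(sites) == 0L) {
    sites$in_domain <- logical()
    sites$domain <- character()
    return(list(sites = sites, fraction_in_domain = 0))
  }
  match_protein <- "protein_id" %in% names(sites) &&
    "protein_id" %in% names(domains)
  hit <- vapply(seq_len(nrow(sites)), function(i) {
    cand <- domains
    if (match_protein) {
      cand <- cand[cand$protein_id == sites$protein_id[i], , drop = FALSE]
    }
    j <- which(sites$position[i] >= cand$start & sites$position[i] <= cand$end)
    if (length(j) == 0L) NA_character_ else cand$name[j[1]]
  }, character(1))
  sites$in_domain <- !is.na(hit)
  sites$domain <- hit
  list(sites = sites, fraction_in_domain = mean(sites$in_domain))
}

#' Build a charge specification for an N-terminal window
#'
#' Counting rules for the local electrostatic model of an N-terminal region:
#' the free N-terminus contributes +1; lysine and arginine +1; aspartate and
#' glutamate -1; a phosphorylatable serine, counted in its phosphorylated
#' state, -2; a serine-to-alanine (phosphonull) mutation 0; a
#' serine-to-aspartate (phosphomimetic) mutation -1; histidine and all other
#' residues 0.
#'
#' @param sequence Protein sequence (at least covering the window).
#' @param window `c(start, end)` of the modeled region, default residues
#'   1-15.
#' @param phospho_positions Positions of phosphorylatable serines within the
#'   window.
#' @param mutations Named character vector mapping position to `"A"` or
#'   `"D"`; only phosphorylatable-serine positions may be mutated.
#' @return List of class `charge_spec`.
#' @export
charge_spec <- function(sequence, window = c(1L, 15L),
                        phospho_positions = integer(),
                        mutations = character()) {
  res <- strsplit(sequence, "")[[1]]
  if (window[1] < 1L || window[2] > length(res) || window[1] > window[2]) {
    stop("window outside protein")
  }
  phospho_positions <- as.integer(phospho_positions)
  if (any(res[phospho_positions] != "S")) {
    stop("phosphorylatable positions must be serine")
  }
  mut_pos <- as.integer(names(mutations))
  if (length(mutations) > 0L) {
    if (!all(mutations %in% c("A", "D"))) {
      stop("invalid mutation: only S->A and S->D are modeled")
    }
    if (!all(mut_pos %in% phospho_positions)) {
      stop("invalid mutation: position is not a phosphorylatable serine")
    }
  }
  structure(list(residues = res, window = as.integer(window),
                 phospho_positions = phospho_positions,
                 mutations = mutations),
            class = "charge_spec")
}

#' Net local charge of an N-terminal window
#'
#' Applies the [charge_spec()] counting rules and returns the integer net
#' charge of the window.
#'
#' @param spec A [charge_spec()].
#' @return Integer net charge.
#' @export
net_charge <- function(spec) {
  stopifnot(inherits(spec, "charge_spec"))
  idx <- spec$window[1]:spec$window[2]
  mut_pos <- as.integer(names(spec$mutations))
  per_residue <- vapply(idx, function(i) {
    r <- spec$residues[i]
    if (i %in% mut_pos) {
      switch(spec$mutations[[as.character(i)]], A = 0, D = -1)
    } else if (i %in% spec$phospho_positions) {
      -2  # phosphoserine: two potential negative charges
    } else if (r %in% c("K", "R")) {
      1
    } else if (r %in% c("D", "E")) {
      -1
    } else {
      0
    }
  }, numeric(1))
  nterm <- if (spec$window[1] == 1L) 1 else 0
  as.integer(nterm + sum(per_residue))
}

#' Model Set2p N-terminal window
#'
#' Builds the 15-residue N-terminal window of the H3K36 methyltransferase
#' Set2p from its documented charge-bearing features: a lysine at position 3,
#' phosphorylatable serines at positions 6, 8 and 10, and the EDEKE acidic
#' patch at residues 11-15. Positions without a documented charge feature are
#' filled with neutral glycine/alanine placeholders, so this is a
#' feature-faithful model window (its net charge depends only on the
#' documented features), not the full native sequence.
#'
#' @param mutations Named character vector of S->A / S->D substitutions at
#'   positions 6, 8, 10 (e.g. `c("6" = "A")`).
#' @return A [charge_spec()] for residues 1-15.
#' @export
set2_nterm_window <- function(mutations = character()) {
  seq15 <- "MGKAASGSGSEDEKE"  # K3, S6/S8/S10, EDEKE at 11-15
  charge_spec(seq15, window = c(1L, 15L),
              phospho_positions = c(6L, 8L, 10L),
              mutations = mutations)
}
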