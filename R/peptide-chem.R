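#' Construct a peptidoform
#'
#' A peptidoform is a peptide sequence together with a set of positioned
#' modifications and (optionally) a charge state. Positions are 1-based
#' residue indices; position 0 denotes the peptide N-terminus.
#'
#' @param sequence Character scalar over the 20 one-letter residue codes.
#' @param mods data.frame with columns `position` (integer) and `name`
#'   (registry modification name), or NULL for an unmodified peptide.
#' @param charge Positive integer charge state z, or NA if not yet assigned.
#' @param registry Modification registry (see [modification_registry()]).
#' @return Object of class `peptidoform`.
#' @export
peptidoform <- function(sequence, mods = NULL, charge = NA_integer_,
                        registry = modification_registry()) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  res <- strsplit(sequence, "")[[1]]
  unknown <- setdiff(res, names(amino_acid_masses()))
  if (length(unknown) > 0L) {
    stop("invalid sequence: unknown residue code(s) ",
         paste(unique(unknown), collapse = ", "))
  }
  if (is.null(mods)) {
    mods <- data.frame(position = integer(), name = character())
  }
  stopifnot(is.data.frame(mods), all(c("position", "name") %in% names(mods)))
  mods$position <- as.integer(mods$position)
  if (nrow(mods) > 0L) {
    if (any(mods$position < 0L | mods$position > nchar(sequence))) {
      stop("modification position outside sequence bounds")
    }
    i <- match(mods$name, registry$name)
    if (anyNA(i)) {
      stop("unknown modification(s): ",
           paste(unique(mods$name[is.na(i)]), collapse = ", "))
    }
    target <- ifelse(mods$position == 0L, "N-term", res[pmax(mods$position, 1L)])
    ok <- mapply(function(t, j) t %in% registry$targets[[j]], target, i)
    if (!all(ok)) {
      bad <- which(!ok)[1L]
      stop("modification '", mods$name[bad], "' not applicable to target '",
           target[bad], "' at position ", mods$position[bad])
    }
  }
  if (!is.na(charge) && charge < 1) stop("invalid charge: z must be >= 1")
  structure(
    list(sequence = sequence, mods = mods[order(mods$position, mods$name), ,
                                          drop = FALSE],
         charge = as.integer(charge)),
    class = "peptidoform"
  )
}

#' @export
print.peptidoform <- function(x, ...) {
  modstr <- if (nrow(x$mods) == 0L) "none" else
    paste(sprintf("%s@%d", x$mods$name, x$mods$position), collapse = ", ")
  cat(sprintf("<peptidoform> %s  z=%s  mods: %s\n", x$sequence,
              ifelse(is.na(x$charge), "?", x$charge), modstr))
  invisible(x)
}

#' Monoisotopic mass of a peptidoform
#'
#' Sum of the residue masses, one water, and the modification mass shifts.
#'
#' @param pf A [peptidoform()].
#' @param masses Residue mass table.
#' @param registry Modification registry.
#' @return Neutral monoisotopic mass in Da.
#' @export
monoisotopic_mass <- function(pf, masses = amino_acid_masses(),
                              registry = modification_registry()) {
  stopifnot(inherits(pf, "peptidoform"))
  res <- strsplit(pf$sequence, "")[[1]]
  m <- masses[res]
  if (anyNA(m)) {
    stop("invalid sequence: unknown residue code(s) ",
         paste(unique(res[is.na(m)]), collapse = ", "))
  }
  sum(m) + water_mass() +
    if (nrow(pf$mods) > 0L) sum(mod_delta(pf$mods$name, registry)) else 0
}

#' Mass-to-charge ratio of a peptidoform
#'
#' `(M + z * m_proton) / z` for the peptidoform's charge state. The reporting
#' convention in figures rounds to 2 decimals; the returned value is
#' unrounded.
#'
#' @inheritParams monoisotopic_mass
#' @return m/z in Thomson.
#' @export
mz <- function(pf, masses = amino_acid_masses(),
               registry = modification_registry()) {
  stopifnot(inherits(pf, "peptidoform"))
  z <- pf$charge
  if (is.na(z) || z < 1) stop("invalid charge: z must be >= 1")
  (monoisotopic_mass(pf, masses, registry) + z * proton_mass()) / z
}

#' Apply histone propionylation chemistry to a peptide
#'
#' In-gel propionylation derivatizes free lysine epsilon-amines (and,
#' optionally, the peptide N-terminus). A lysine's capacity to accept a
#' propionyl group depends on its methylation state: unmethylated and
#' monomethylated lysines are propionylated (a monomethyl lysine then carries
#' methyl + propionyl), while di- and tri-methylated lysines have no free
#' amine and carry only their methyl marks.
#'
#' @param sequence Peptide sequence.
#' @param k_methyl_states Named list/vector mapping 1-based lysine position to
#'   one of `"me0"`, `"me1"`, `"me2"`, `"me3"`. Lysines not listed default to
#'   `"me0"`.
#' @param nterm Should the peptide N-terminus be propionylated?
#' @param charge Charge state recorded on the returned peptidoform.
#' @return A [peptidoform()] carrying the propionyl/methyl modifications.
#' @export
propionylate <- function(sequence, k_methyl_states = list(), nterm = FALSE,
                         charge = NA_integer_) {
  res <- strsplit(sequence, "")[[1]]
  pos <- as.integer(names(k_methyl_states))
  states <- unlist(k_methyl_states, use.names = FALSE)
  if (length(pos) > 0L) {
    if (anyNA(pos) || any(pos < 1L | pos > length(res))) {
      stop("invalid state: methyl-state position outside sequence")
    }
    if (any(res[pos] != "K")) {
      stop("invalid state: methyl state assigned to non-lysine residue at ",
           paste(pos[res[pos] != "K"], collapse = ", "))
    }
    if (!all(states %in% c("me0", "me1", "me2", "me3"))) {
      stop("invalid state: methyl states must be me0/me1/me2/me3")
    }
  }
  k_all <- which(res == "K")
  state <- stats::setNames(rep("me0", length(k_all)), k_all)
  state[as.character(pos)] <- states
  mods <- data.frame(position = integer(), name = character())
  for (k in k_all) {
    s <- state[[as.character(k)]]
    add <- switch(s,
      me0 = "propionyl",
      me1 = c("methyl", "propionyl"),
      me2 = "dimethyl",
      me3 = "trimethyl"
    )
    mods <- rbind(mods, data.frame(position = k, name = add))
  }
  if (isTRUE(nterm)) {
    mods <- rbind(mods, data.frame(position = 0L, name = "propionyl"))
  }
  peptidoform(sequence, mods, charge = charge)
}

protease_rules <- function(aspn_residues = c("D", "E")) {
  list(
    trypsin      = list(residues = c("K", "R"), side = "C", no_before = "P"),
    lysarginase  = list(residues = c("K", "R"), side = "N", no_before = NULL),
    aspn         = list(residues = aspn_residues, side = "N", no_before = NULL),
    chymotrypsin = list(residues = c("F", "Y", "W", "L", "K", "R"),
                        side = "C", no_before = "P")
  )
}

#' In-silico proteolytic digestion
#'
#' Fully specific digestion under one of four protease rules:
#' \describe{
#'   \item{trypsin}{cleaves C-terminal to K/R, not before P}
#'   \item{lysarginase}{cleaves N-terminal to K/R}
#'   \item{aspn}{cleaves N-terminal to D and E (configurable to D only)}
#'   \item{chymotrypsin}{TrypChymo specificity: C-terminal to F/Y/W/L/K/R,
#'     not before P}
#' }
#' All products with at most `max_missed` missed cleavages are returned, in
#' order of start coordinate then length.
#'
#' @param protein Protein sequence.
#' @param protease One of `"trypsin"`, `"lysarginase"`, `"aspn"`,
#'   `"chymotrypsin"`.
#' @param max_missed Maximum number of missed cleavages (>= 0).
#' @param aspn_residues Residues recognized by the Asp-N rule.
#' @return data.frame with columns `peptide`, `start`, `end` (1-based
#'   inclusive), `missed_cleavages`.
#' @export
digest <- function(protein, protease, max_missed = 0L,
                   aspn_residues = c("D", "E")) {
  stopifnot(is.character(protein), length(protein) == 1L, nzchar(protein))
  if (max_missed < 0L) stop("max_missed must be >= 0")
  rules <- protease_rules(aspn_residues)
  if (!protease %in% names(rules)) {
    stop("configuration error: unknown protease '", protease, "'")
  }
  rule <- rules[[protease]]
  res <- strsplit(protein, "")[[1]]
  n <- length(res)
  # cut k means a cleavage between residues k and k+1
  if (rule$side == "C") {
    cuts <- which(res %in% rule$residues)
    if (!is.null(rule$no_before)) {
      cuts <- cuts[cuts == n | !(res[pmin(cuts + 1L, n)] %in% rule$no_before)]
    }
  } else {
    cuts <- which(res %in% rule$residues) - 1L
  }
  cuts <- sort(unique(cuts[cuts >= 1L & cuts < n]))
  bounds <- c(0L, cuts, n)
  out <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    for (j in (i + 1L):min(length(bounds), i + 1L + max_missed)) {
      start <- bounds[i] + 1L
      end <- bounds[j]
      out[[length(out) + 1L]] <- data.frame(
        peptide = substr(protein, start, end),
        start = start, end = end,
        missed_cleavages = j - i - 1L
      )
    }
  }
  out <- do.call(rbind, out)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Symmetric ppm tolerance window around an m/z value
#'
#' @param center_mz Center m/z (> 0).
#' @param tol_ppm Tolerance in parts per million (> 0).
#' @return Numeric `c(low, high)`.
#' @export
ppm_window <- function(center_mz, tol_ppm) {
  if (!is.finite(center_mz) || center_mz <= 0 ||
      !is.finite(tol_ppm) || tol_ppm <= 0) {
    stop("invalid argument: center_mz and tol_ppm must be positive")
  }
  c(low = center_mz * (1 - tol_ppm / 1e6),
    high = center_mz * (1 + tol_ppm / 1e6))
}

#' Expected H3K36 methyl-peptidoform series
#'
#' Builds the four triply-charged peptidoforms of the K36-containing tryptic
#' H3 peptide KSAPSTGGVKKPHR after propionyl derivatization, one per K36
#' methylation state (peptide position 10 = H3 K36). me0/me1 forms are triply
#' propionylated (K27, K36, K37 in protein numbering); me2/me3 forms are
#' doubly propionylated because the di/trimethylated lysine has no free amine.
#'
#' @param charge Charge state (default 3, the quantified species).
#' @return Named list of [peptidoform()]s (`me0`..`me3`).
#' @export
h3k36_peptidoforms <- function(charge = 3L) {
  seqs <- "KSAPSTGGVKKPHR"
  states <- c(me0 = "me0", me1 = "me1", me2 = "me2", me3 = "me3")
  lapply(states, function(s) {
    propionylate(seqs, k_methyl_states = stats::setNames(list(s), "10"),
                 nterm = FALSE, charge = charge)
  })
}
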