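#' Read a PSM table
#'
#' The PSM TSV schema has one row per peptide-spectrum match with columns:
#' `protein_id`, `peptide`, `mods` (semicolon-separated `position:name`
#' entries in peptide coordinates, empty for unmodified), `protease`,
#' `fragmentation` (`HCD` or `EThcD`), `ion_score`, `expect_p`, `psm_fdr`,
#' `loc_prob` (semicolon-separated `position:probability` percentages for the
#' localized modified sites), `retention_time`, `precursor_mz`, `charge`.
#'
#' @param path Path to the TSV.
#' @return data.frame with `mods` and `loc_prob` parsed into list columns.
#' @export
read_psm_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  validate_psm_table(parse_psm_columns(tab))
}

parse_pairs <- function(x, value_numeric = TRUE) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(data.frame(position = integer(),
                        value = if (value_numeric) numeric() else character()))
    }
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.frame(
      position = as.integer(vapply(parts, `[`, "", 1L)),
      value = if (value_numeric) as.numeric(vapply(parts, `[`, "", 2L))
              else vapply(parts, `[`, "", 2L)
    )
  })
}

parse_psm_columns <- function(tab) {
  if (is.character(tab$mods) || all(is.na(tab$mods))) {
    tab$mods <- parse_pairs(as.character(tab$mods), value_numeric = FALSE)
  }
  if (is.character(tab$loc_prob) || all(is.na(tab$loc_prob))) {
    tab$loc_prob <- parse_pairs(as.character(tab$loc_prob))
  }
  tab
}

psm_required_cols <- c(
  "protein_id", "peptide", "mods", "protease", "fragmentation",
  "ion_score", "expect_p", "psm_fdr", "loc_prob", "charge"
)

validate_psm_table <- function(tab) {
  missing <- setdiff(psm_required_cols, names(tab))
  if (length(missing) > 0L) {
    stop("PSM table schema error: missing required field(s) ",
         paste(missing, collapse = ", "))
  }
  tab
}

#' Filter PSMs by the survey's quality thresholds
#'
#' A PSM for a modified peptide is retained iff its FDR is strictly below
#' `fdr`, its ion score is at least `score`, its expectation value is
#' strictly below `expect`, and every reported modified-site localization
#' probability is at least `locprob` percent. A PSM failing any criterion is
#' discarded entirely, including all sites it reports.
#'
#' @param records PSM data.frame (see [read_psm_table()]).
#' @param thresholds Named list: `fdr` (default 0.01), `score` (30),
#'   `expect` (0.05), `locprob` (95).
#' @return The surviving subset, same schema, original order preserved.
#' @export
filter_psms <- function(records,
                        thresholds = list(fdr = 0.01, score = 30,
                                          expect = 0.05, locprob = 95)) {
  records <- validate_psm_table(parse_psm_columns(records))
  th <- utils::modifyList(list(fdr = 0.01, score = 30, expect = 0.05,
                               locprob = 95), as.list(thresholds))
  if (any(unlist(th) < 0)) stop("thresholds must be non-negative")
  loc_ok <- vapply(records$loc_prob, function(lp) {
    nrow(lp) == 0L || all(lp$value >= th$locprob)
  }, logical(1))
  keep <- records$psm_fdr < th$fdr &
    records$ion_score >= th$score &
    records$expect_p < th$expect &
    loc_ok
  records[keep, , drop = FALSE]
}

#' Collate filtered PSMs into peptidoforms and unique modification sites
#'
#' Maps each PSM's peptide into its protein (exact substring match),
#' deduplicates peptidoforms on (sequence, modification set) and sites on
#' (protein, position, modification type), aggregates the
#' (protease, fragmentation) evidence observed for each site, and flags
#' novelty against an optional known-site list.
#'
#' @param filtered Filtered PSM data.frame.
#' @param proteins Named character vector of protein sequences (names =
#'   protein_id), e.g. from [read_fasta()].
#' @param known_sites Optional data.frame with columns `protein_id`,
#'   `position`, `ptm_type` (and optionally `source`).
#' @return List with `sites` (one row per unique site: `protein_id`,
#'   `position`, `residue`, `ptm_type`, `n_psms`, `evidence` list column of
#'   protease/fragmentation pairs, `novelty`), `peptidoforms` (deduplicated),
#'   and `summary` (per-protein peptidoform and site counts).
#' @export
collate_sites <- function(filtered, proteins, known_sites = NULL) {
  filtered <- validate_psm_table(parse_psm_columns(filtered))
  if (nrow(filtered) == 0L) {
    empty_sites <- data.frame(protein_id = character(), position = integer(),
                              residue = character(), ptm_type = character(),
                              n_psms = integer(), novelty = character())
    empty_sites$evidence <- list()
    return(list(sites = empty_sites, peptidoforms = filtered[0, ],
                summary = data.frame(protein_id = character(),
                                     n_nonredundant_peptidoforms = integer(),
                                     n_unique_sites = integer())))
  }
  starts <- integer(nrow(filtered))
  for (i in seq_len(nrow(filtered))) {
    prot <- proteins[[filtered$protein_id[i]]]
    if (is.null(prot)) {
      stop("mapping error: protein '", filtered$protein_id[i], "' not supplied")
    }
    p <- regexpr(filtered$peptide[i], prot, fixed = TRUE)
    if (p < 0) {
      stop("mapping error: peptide '", filtered$peptide[i],
           "' not found in protein '", filtered$protein_id[i], "'")
    }
    starts[i] <- as.integer(p)
  }
  mods_key <- vapply(filtered$mods, function(m) {
    if (nrow(m) == 0L) "" else
      paste(sprintf("%d:%s", m$position, m$value), collapse = ";")
  }, character(1))
  pf_key <- paste(filtered$protein_id, filtered$peptide, mods_key, sep = "|")
  peptidoforms <- filtered[!duplicated(pf_key), , drop = FALSE]

  site_rows <- list()
  for (i in seq_len(nrow(filtered))) {
    m <- filtered$mods[[i]]
    if (nrow(m) == 0L) next
    site_rows[[length(site_rows) + 1L]] <- data.frame(
      protein_id = filtered$protein_id[i],
      position = starts[i] + m$position - 1L,
      ptm_type = m$value,
      protease = filtered$protease[i],
      fragmentation = filtered$fragmentation[i]
    )
  }
  if (length(site_rows) == 0L) {
    sites <- data.frame(protein_id = character(), position = integer(),
                        residue = character(), ptm_type = character(),
                        n_psms = integer(), novelty = character())
    sites$evidence <- list()
  } else {
    obs <- do.call(rbind, site_rows)
    key <- paste(obs$protein_id, obs$position, obs$ptm_type, sep = "|")
    first <- !duplicated(key)
    sites <- obs[first, c("protein_id", "position", "ptm_type"), drop = FALSE]
    sites$residue <- substr(proteins[sites$protein_id], sites$position,
                            sites$position)
    sites$n_psms <- as.integer(table(key)[key[first]])
    sites$evidence <- lapply(key[first], function(k) {
      unique(obs[key == k, c("protease", "fragmentation"), drop = FALSE])
    })
    sites$novelty <- "novel"
    if (!is.null(known_sites) && nrow(known_sites) > 0L) {
      known_key <- paste(known_sites$protein_id, known_sites$position,
                         known_sites$ptm_type, sep = "|")
      sites$novelty[key[first] %in% known_key] <- "known"
    }
    sites <- sites[order(sites$protein_id, sites$position, sites$ptm_type), ,
                   drop = FALSE]
    rownames(sites) <- NULL
  }
  prot_ids <- sort(unique(filtered$protein_id))
  summary <- data.frame(
    protein_id = prot_ids,
    n_nonredundant_peptidoforms = vapply(prot_ids, function(p)
      sum(peptidoforms$protein_id == p), integer(1)),
    n_unique_sites = vapply(prot_ids, function(p)
      sum(sites$protein_id == p), integer(1))
  )
  rownames(summary) <- NULL
  list(sites = sites, peptidoforms = peptidoforms, summary = summary)
}

#' Read a known-site list
#'
#' Plain TSV with columns `protein_id`, `position`, `ptm_type` and optionally
#' `source`, as used for literature collations of modification sites.
#'
#' @param path Path to the TSV.
#' @return data.frame.
#' @export
read_known_sites <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
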