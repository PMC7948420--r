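#' Admit kinase-substrate edges from motif-prediction scores
#'
#' A motif-prediction record (e.g. a NetworKIN-style kinase recognition
#' score) yields an edge iff its score is strictly greater than `threshold`.
#'
#' @param records data.frame with columns `regulator`, `substrate`, `site`
#'   (optional, NA for protein-level), `score`.
#' @param threshold Admission threshold (default 2, strict `>`).
#' @return data.frame of admitted edges with `evidence_type =
#'   "motif_prediction"`.
#' @export
admit_motif <- function(records, threshold = 2) {
  if (!"score" %in% names(records) || any(is.na(records$score))) {
    stop("schema error: missing score")
  }
  out <- records[records$score > threshold, , drop = FALSE]
  out$evidence_type <- rep("motif_prediction", nrow(out))
  out
}

#' Admit edges from perturbation phosphoproteomics
#'
#' Significant phosphopeptide abundance changes in single-gene deletion
#' strains: deleting a kinase should lower its substrate's phosphopeptide
#' (fold-change < -1.5), deleting a phosphatase should raise it
#' (fold-change > 1.5); both require p < 0.05. Fold-changes are interpreted
#' on the signed linear scale as reported.
#'
#' @param records data.frame with columns `regulator`, `regulator_class`
#'   (`kinase` or `phosphatase`), `substrate`, `site`, `fold_change`,
#'   `p_value`.
#' @param p_max,fc_min Thresholds (defaults 0.05 and 1.5).
#' @return data.frame of admitted edges with `evidence_type =
#'   "quant_perturbation"`.
#' @export
admit_quant <- function(records, p_max = 0.05, fc_min = 1.5) {
  needed <- c("regulator_class", "fold_change", "p_value")
  if (!all(needed %in% names(records))) {
    stop("schema error: missing ", paste(setdiff(needed, names(records)),
                                         collapse = ", "))
  }
  if (!all(records$regulator_class %in% c("kinase", "phosphatase"))) {
    stop("unknown regulator class: ",
         paste(unique(setdiff(records$regulator_class,
                              c("kinase", "phosphatase"))), collapse = ", "))
  }
  keep <- records$p_value < p_max &
    ifelse(records$regulator_class == "kinase",
           records$fold_change < -fc_min,
           records$fold_change > fc_min)
  out <- records[keep, , drop = FALSE]
  out$evidence_type <- rep("quant_perturbation", nrow(out))
  out
}

edge_key <- function(df) {
  site <- if ("site" %in% names(df)) as.character(df$site) else
    rep(NA_character_, nrow(df))
  site[is.na(site)] <- ""
  paste(df$regulator, df$substrate, site, sep = "|")
}

#' Assemble the draft regulatory network
#'
#' Merges admitted motif and perturbation edges with physical-interaction
#' records, deduplicating on (regulator, substrate, site) and aggregating
#' evidence types. Genetic-interaction records never create an edge on their
#' own; they only corroborate an edge (matched on regulator and substrate)
#' that is already supported by a non-genetic evidence line. Regulators whose
#' admitted edges touch two or more distinct substrate enzymes are flagged as
#' multi-substrate.
#'
#' @param motif_edges,quant_edges Admitted edges from [admit_motif()] /
#'   [admit_quant()].
#' @param physical Optional data.frame of physical-interaction records
#'   (`regulator`, `substrate`, optional `site`); admitted unconditionally as
#'   `physical_interaction` evidence.
#' @param genetic Optional data.frame of genetic-interaction records
#'   (`regulator`, `substrate`).
#' @return List of class `regulatory_network`: `edges` (regulator, substrate,
#'   site, `evidence` list column, `corroborated_genetic`), `nodes`
#'   (id, role, `multi_substrate` flag for regulators).
#' @export
assemble_network <- function(motif_edges = NULL, quant_edges = NULL,
                             physical = NULL, genetic = NULL) {
  pieces <- list()
  add <- function(df, type) {
    if (is.null(df) || nrow(df) == 0L) return()
    df$site <- if ("site" %in% names(df)) as.character(df$site) else NA_character_
    df$evidence_type <- type
    pieces[[length(pieces) + 1L]] <<-
      df[, c("regulator", "substrate", "site", "evidence_type")]
  }
  add(motif_edges, "motif_prediction")
  add(quant_edges, "quant_perturbation")
  add(physical, "physical_interaction")
  all_ev <- if (length(pieces) > 0L) do.call(rbind, pieces) else
    data.frame(regulator = character(), substrate = character(),
               site = character(), evidence_type = character())
  key <- edge_key(all_ev)
  first <- !duplicated(key)
  edges <- all_ev[first, c("regulator", "substrate", "site"), drop = FALSE]
  edges$evidence <- lapply(key[first], function(k)
    sort(unique(all_ev$evidence_type[key == k])))
  edges$corroborated_genetic <- rep(FALSE, nrow(edges))
  if (!is.null(genetic) && nrow(genetic) > 0L && nrow(edges) > 0L) {
    gk <- paste(genetic$regulator, genetic$substrate, sep = "|")
    ek <- paste(edges$regulator, edges$substrate, sep = "|")
    edges$corroborated_genetic <- ek %in% gk
  }
  rownames(edges) <- NULL
  regs <- unique(edges$regulator)
  multi <- vapply(regs, function(r)
    length(unique(edges$substrate[edges$regulator == r])) >= 2L, logical(1))
  subs <- unique(edges$substrate)
  nodes <- rbind(
    data.frame(id = regs, role = rep("regulator", length(regs)),
               multi_substrate = unname(multi)),
    data.frame(id = subs, role = rep("enzyme", length(subs)),
               multi_substrate = rep(FALSE, length(subs)))
  )
  rownames(nodes) <- NULL
  structure(list(edges = edges, nodes = nodes), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network> %d edges, %d regulators (%d multi-substrate), %d enzymes\n",
              nrow(x$edges), sum(x$nodes$role == "regulator"),
              sum(x$nodes$multi_substrate), sum(x$nodes$role == "enzyme")))
  invisible(x)
}

#' Export a network as flat node/edge tables
#'
#' @param network A `regulatory_network`.
#' @return List with `edges` (evidence collapsed to a semicolon-joined
#'   string) and `nodes`, both plain data.frames writable as TSV and directly
#'   loadable into GraphML converters.
#' @export
network_tables <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  edges <- network$edges
  edges$evidence <- vapply(edges$evidence, paste, character(1), collapse = ";")
  list(edges = edges, nodes = network$nodes)
}
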