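#' Write a self-contained synthetic fixture directory
#'
#' Generates every input the pipeline consumes — protein FASTA, PSM table,
#' XIC trace pairs, disorder track, domain table, methylation-state counts,
#' and evidence tables — from a single global seed (fanned out per generator
#' via [child_seed()]), alongside a `ground_truth.json` recording the planted
#' parameters.
#'
#' @param dir Output directory (created if missing).
#' @param seed Global integer seed.
#' @param n_sites Number of planted phosphosites.
#' @param occupancies Planted occupancies for the XIC pairs.
#' @param beta Named strain effects for the methylation generator (reference
#'   `WT` = 0).
#' @return Invisibly, the ground-truth list.
#' @export
make_fixtures <- function(dir, seed = 1L, n_sites = 10L,
                          occupancies = c(0.001, 0.05, 0.26),
                          beta = c(WT = 0, mutant = 1.5)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prot <- gen_protein(400L, seed = child_seed(seed, "protein"))
  write_fasta(stats::setNames(prot$sequence, prot$id),
              file.path(dir, "proteins.fasta"))

  res <- strsplit(prot$sequence, "")[[1]]
  sty <- which(res %in% c("S", "T", "Y"))
  withr_seed(child_seed(seed, "sites"))
  pos <- sort(sample(sty, n_sites))
  true_sites <- data.frame(position = pos, ptm_type = "phospho")
  psm <- gen_psm_table(prot, true_sites, n_true = 3L, n_decoy = 12L,
                       noise_prob = 0, seed = child_seed(seed, "psms"))
  write_tsv(psm$psms, file.path(dir, "psms.tsv"))

  for (i in seq_along(occupancies)) {
    pair <- gen_xic_pair(occupancies[i], seed = child_seed(seed, paste0("xic", i)))
    write_tsv(data.frame(rt = pair$modified$rt,
                         intensity = pair$modified$intensity),
              file.path(dir, sprintf("xic_%02d_modified.tsv", i)))
    write_tsv(data.frame(rt = pair$unmodified$rt,
                         intensity = pair$unmodified$intensity),
              file.path(dir, sprintf("xic_%02d_unmodified.tsv", i)))
  }

  withr_seed(child_seed(seed, "disorder"))
  n <- nchar(prot$sequence)
  scores <- pmin(pmax(stats::filter(stats::runif(n), rep(1 / 9, 9),
                                    circular = TRUE), 0), 1)
  write_tsv(data.frame(position = seq_len(n), score = round(as.numeric(scores), 4)),
            file.path(dir, "disorder.tsv"))

  domains <- data.frame(protein_id = prot$id,
                        name = c("SET", "PHD"),
                        start = c(50L, 300L), end = c(150L, 340L),
                        class = c("catalytic", "interaction"))
  write_tsv(domains, file.path(dir, "domains.tsv"))

  meth <- gen_methyl_counts(beta, seed = child_seed(seed, "methyl"))
  write_tsv(meth$counts, file.path(dir, "methyl_counts.tsv"))

  planted_edges <- data.frame(
    regulator = c("KIN1", "KIN1", "KIN2", "PPH1"),
    regulator_class = c("kinase", "kinase", "kinase", "phosphatase"),
    substrate = c(prot$id, "ENZYME2", prot$id, prot$id),
    site = as.character(c(pos[1], NA, pos[2], pos[1])),
    evidence_type = c("motif_prediction", "motif_prediction",
                      "physical_interaction", "quant_perturbation"))
  ev <- gen_evidence_tables(planted_edges, n_noise = 5L,
                            genetic = data.frame(regulator = c("KIN1", "GENONLY"),
                                                 substrate = c(prot$id, prot$id)),
                            seed = child_seed(seed, "evidence"))
  write_tsv(ev$motif, file.path(dir, "evidence_motif.tsv"))
  write_tsv(ev$quant, file.path(dir, "evidence_quant.tsv"))
  write_tsv(ev$physical, file.path(dir, "evidence_physical.tsv"))
  write_tsv(ev$genetic, file.path(dir, "evidence_genetic.tsv"))

  truth <- list(seed = seed, protein_id = prot$id,
                planted_sites = true_sites,
                occupancies = occupancies,
                methyl = meth$truth,
                network = planted_edges)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth)
}

default_thresholds <- function() {
  list(fdr = 0.01, ion_score = 30, expect = 0.05, locprob = 95,
       xic_ppm = 10, disorder = 0.5, networkin = 2, quant_p = 0.05, fc = 1.5)
}

#' Run the full survey pipeline from one configuration
#'
#' Executes the stages in dependency order — PSM filtering, site collation,
#' coverage mapping, XIC occupancy quantification, disorder/domain
#' contextualization, proportional-odds methylation statistics, and network
#' assembly — writing per-stage TSV/JSON outputs plus a run report with an
#' md5-checksummed output manifest. A failure in one stage halts its
#' dependents with a diagnostic naming the stage.
#'
#' @param config Named list (or path to a YAML file) with entries
#'   `input_dir` (a fixture-style directory, see [make_fixtures()]),
#'   `output_dir`, optional `thresholds` overrides (keys as in the printed
#'   defaults: fdr 0.01, ion_score 30, expect 0.05, locprob 95, xic_ppm 10,
#'   disorder 0.5, networkin 2, quant_p 0.05, fc 1.5), optional `seed`.
#' @return The run report (list), invisibly written as `run_report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$input_dir), !is.null(config$output_dir))
  th <- utils::modifyList(default_thresholds(),
                          as.list(config$thresholds %||% list()))
  ind <- config$input_dir
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = config, thresholds = th, stages = list())
  outputs <- character()
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    report$stages[[name]] <<- res
    res
  }

  proteins <- read_fasta(file.path(ind, "proteins.fasta"))

  filtered <- stage("filter", function() {
    psms <- read_psm_table(file.path(ind, "psms.tsv"))
    kept <- filter_psms(psms, thresholds = list(
      fdr = th$fdr, score = th$ion_score, expect = th$expect,
      locprob = th$locprob))
    write_psm_table(kept, file.path(out, "psms_filtered.tsv"))
    outputs <<- c(outputs, "psms_filtered.tsv")
    list(n_input = nrow(psms), n_retained = nrow(kept), psms = kept)
  })

  collated <- stage("collate", function() {
    res <- collate_sites(filtered$psms, proteins)
    sites_flat <- res$sites
    if (nrow(sites_flat) > 0L) {
      sites_flat$evidence <- vapply(sites_flat$evidence, function(e)
        paste(sprintf("%s/%s", e$protease, e$fragmentation), collapse = ";"),
        character(1))
    }
    write_tsv(sites_flat, file.path(out, "sites.tsv"))
    outputs <<- c(outputs, "sites.tsv")
    list(summary = res$summary, n_sites = nrow(res$sites), sites = res$sites)
  })

  stage("coverage", function() {
    psms <- filtered$psms
    profs <- lapply(names(proteins), function(pid) {
      sub <- psms[psms$protein_id == pid, , drop = FALSE]
      if (nrow(sub) == 0L) return(NULL)
      prof <- map_peptides(proteins[[pid]],
                           data.frame(peptide = sub$peptide,
                                      experiment = paste(sub$protease,
                                                         sub$fragmentation)),
                           protein_id = pid)
      tabs <- coverage_tables(prof)
      write_tsv(tabs$depth_track,
                file.path(out, sprintf("coverage_depth_%s.tsv", pid)))
      outputs <<- c(outputs, sprintf("coverage_depth_%s.tsv", pid))
      tabs$summary
    })
    cov <- do.call(rbind, profs)
    if (!is.null(cov)) {
      write_tsv(cov, file.path(out, "coverage_summary.tsv"))
      outputs <<- c(outputs, "coverage_summary.tsv")
    }
    list(coverage = cov)
  })

  stage("quant", function() {
    mods <- sort(list.files(ind, pattern = "^xic_\\d+_modified\\.tsv$"))
    if (length(mods) == 0L) return(list(n_pairs = 0L))
    occ <- vapply(mods, function(f) {
      um <- sub("modified", "unmodified", f)
      pm <- integrate_peak(read_trace(file.path(ind, f), tol_ppm = th$xic_ppm))
      pu <- integrate_peak(read_trace(file.path(ind, um), tol_ppm = th$xic_ppm))
      as.numeric(occupancy(pm$area, pu$area))
    }, numeric(1))
    tab <- data.frame(pair = sub("_modified\\.tsv$", "", mods),
                      occupancy = round(unname(occ), 4))
    write_tsv(tab, file.path(out, "occupancy.tsv"))
    outputs <<- c(outputs, "occupancy.tsv")
    list(n_pairs = length(occ), occupancy = tab)
  })

  stage("context", function() {
    sites <- collated$sites
    track <- read_disorder_track(file.path(ind, "disorder.tsv"),
                                 threshold = th$disorder)
    dis <- disorder_context(sites, track)
    domains <- read_domains(file.path(ind, "domains.tsv"))
    dom <- domain_context(dis$sites, domains)
    flat <- dom$sites
    flat$evidence <- NULL
    write_tsv(flat, file.path(out, "sites_context.tsv"))
    outputs <<- c(outputs, "sites_context.tsv")
    list(disorder_tally = dis$tally, fraction_in_domain = dom$fraction_in_domain)
  })

  stage("stats", function() {
    path <- file.path(ind, "methyl_counts.tsv")
    if (!file.exists(path)) return(list(skipped = "no methylation counts"))
    counts <- read_methyl_counts(path)
    fit <- fit_proportional_odds(counts, counts_mode = TRUE)
    alt <- fit_adjacent_category(counts, counts_mode = TRUE)
    lrt <- lr_test(fit, alt)
    or_tab <- odds_ratio_table(fit)
    write_tsv(or_tab, file.path(out, "methyl_odds_ratios.tsv"))
    outputs <<- c(outputs, "methyl_odds_ratios.tsv")
    list(odds_ratios = or_tab, lr_test = lrt,
         cutpoints = fit$cutpoints, logLik = fit$logLik)
  })

  stage("network", function() {
    motif <- utils::read.delim(file.path(ind, "evidence_motif.tsv"))
    quant <- utils::read.delim(file.path(ind, "evidence_quant.tsv"))
    phys_path <- file.path(ind, "evidence_physical.tsv")
    gen_path <- file.path(ind, "evidence_genetic.tsv")
    physical <- if (file.exists(phys_path)) utils::read.delim(phys_path) else NULL
    genetic <- if (file.exists(gen_path)) utils::read.delim(gen_path) else NULL
    net <- assemble_network(admit_motif(motif, th$networkin),
                            admit_quant(quant, th$quant_p, th$fc),
                            physical, genetic)
    tabs <- network_tables(net)
    write_tsv(tabs$edges, file.path(out, "network_edges.tsv"))
    write_tsv(tabs$nodes, file.path(out, "network_nodes.tsv"))
    outputs <<- c(outputs, "network_edges.tsv", "network_nodes.tsv")
    list(n_edges = nrow(net$edges),
         multi_substrate = net$nodes$id[net$nodes$multi_substrate])
  })

  manifest <- data.frame(
    file = outputs,
    md5 = unname(tools::md5sum(file.path(out, outputs))))
  report$manifest <- manifest
  report_out <- report
  report_out$stages <- lapply(report_out$stages, strip_heavy)
  jsonlite::write_json(report_out, file.path(out, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

strip_heavy <- function(x) {
  x$psms <- NULL
  x$sites <- NULL
  x
}
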