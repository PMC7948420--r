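#' Deterministic child seed derivation
#'
#' Fans a global seed out to per-generator child seeds so that each fixture
#' can be regenerated independently. The child seed is
#' `(seed * 1009 + sum of UTF-8 codes of tag) mod (2^31 - 1)`.
#'
#' @param seed Integer global seed.
#' @param tag Character tag naming the generator.
#' @return Integer child seed in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag))
  as.integer((as.numeric(seed) * 1009 + h) %% (2^31 - 1))
}

#' Generate a random protein sequence
#'
#' @param length Sequence length (> 0).
#' @param composition Optional named probability vector over residue codes;
#'   default uniform over the 20 standard residues.
#' @param seed Integer seed.
#' @return List: `id`, `sequence`.
#' @export
gen_protein <- function(length, composition = NULL, seed = 1L) {
  stopifnot(length > 0)
  aa <- names(amino_acid_masses())
  if (is.null(composition)) {
    composition <- stats::setNames(rep(1 / 20, 20), aa)
  }
  composition <- composition / sum(composition)
  withr_seed(seed)
  list(id = sprintf("synthetic_protein_%d", seed),
       sequence = paste(sample(names(composition), length, replace = TRUE,
                               prob = composition), collapse = ""))
}

# set the RNG locally and restore on exit of the caller
withr_seed <- function(seed) {
  set.seed(as.integer(seed %% (2^31 - 1)))
  invisible(seed)
}

#' Generate a PSM table with planted modification sites
#'
#' Emits `n_true` PSMs per planted site with quality metrics drawn above the
#' filter thresholds with probability `1 - noise_prob` (and deliberately
#' failing exactly one randomly chosen criterion otherwise), plus `n_decoy`
#' decoy-like PSMs that each fail at least one criterion, so that every
#' filter is exercised. Peptides are tryptic peptides of the protein covering
#' the planted site.
#'
#' @param protein List with `id` and `sequence` (e.g. from [gen_protein()]).
#' @param true_sites data.frame with `position` and `ptm_type` (positions on
#'   residues compatible with the modification).
#' @param n_true PSMs per planted site.
#' @param n_decoy Number of failing PSMs.
#' @param noise_prob Probability that a true-site PSM fails one criterion.
#' @param seed Integer seed.
#' @return List: `psms` (PSM data.frame in the [read_psm_table()] schema) and
#'   `truth` (the planted site table).
#' @export
gen_psm_table <- function(protein, true_sites, n_true = 3L, n_decoy = 10L,
                          noise_prob = 0, seed = 1L) {
  withr_seed(seed)
  peps <- digest(protein$sequence, "trypsin", max_missed = 1L)
  proteases <- c("trypsin", "lysarginase", "aspn", "chymotrypsin")
  frags <- c("HCD", "EThcD")
  rows <- list()
  emit <- function(pep_row, mods, passing, fail_criterion = NULL) {
    ion <- stats::runif(1, 35, 90)
    fdr <- stats::runif(1, 0, 0.008)
    expect <- stats::runif(1, 1e-6, 0.04)
    loc <- stats::runif(nrow(mods), 96, 100)
    if (!passing) {
      switch(fail_criterion,
             score = ion <- stats::runif(1, 5, 29.5),
             fdr = fdr <- stats::runif(1, 0.011, 0.2),
             expect = expect <- stats::runif(1, 0.051, 0.5),
             locprob = loc[1] <- stats::runif(1, 20, 94.5))
    }
    data.frame(
      protein_id = protein$id,
      peptide = pep_row$peptide,
      mods = if (nrow(mods) == 0L) "" else
        paste(sprintf("%d:%s", mods$position, mods$name), collapse = ";"),
      protease = sample(proteases, 1),
      fragmentation = sample(frags, 1),
      ion_score = round(ion, 2),
      expect_p = signif(expect, 3),
      psm_fdr = signif(fdr, 3),
      loc_prob = if (nrow(mods) == 0L) "" else
        paste(sprintf("%d:%.1f", mods$position, loc), collapse = ";"),
      retention_time = round(stats::runif(1, 5, 90), 2),
      precursor_mz = round(stats::runif(1, 300, 1200), 4),
      charge = sample(2:4, 1)
    )
  }
  for (k in seq_len(nrow(true_sites))) {
    pos <- true_sites$position[k]
    cand <- peps[peps$start <= pos & peps$end >= pos, , drop = FALSE]
    if (nrow(cand) == 0L) stop("planted site ", pos, " not covered by any tryptic peptide")
    for (r in seq_len(n_true)) {
      pep_row <- cand[sample(nrow(cand), 1), , drop = FALSE]
      mods <- data.frame(position = pos - pep_row$start + 1L,
                         name = true_sites$ptm_type[k])
      fail <- stats::runif(1) < noise_prob
      rows[[length(rows) + 1L]] <-
        emit(pep_row, mods, passing = !fail,
             fail_criterion = sample(c("score", "fdr", "expect", "locprob"), 1))
    }
  }
  # decoys: unmodified or off-site modified PSMs failing exactly one criterion
  for (d in seq_len(n_decoy)) {
    pep_row <- peps[sample(nrow(peps), 1), , drop = FALSE]
    res <- strsplit(pep_row$peptide, "")[[1]]
    sty <- which(res %in% c("S", "T", "Y"))
    mods <- if (length(sty) > 0L) {
      data.frame(position = sty[sample(length(sty), 1)], name = "phospho")
    } else {
      data.frame(position = integer(), name = character())
    }
    rows[[length(rows) + 1L]] <-
      emit(pep_row, mods, passing = FALSE,
           fail_criterion = sample(
             if (nrow(mods) > 0L) c("score", "fdr", "expect", "locprob")
             else c("score", "fdr", "expect"), 1))
  }
  list(psms = do.call(rbind, rows), truth = true_sites)
}

gaussian_trace <- function(rt, area, rt_apex, sd_min) {
  area / (sd_min * sqrt(2 * pi)) * exp(-(rt - rt_apex)^2 / (2 * sd_min^2))
}

#' Generate a modified/unmodified XIC trace pair with planted occupancy
#'
#' Two traces on a shared retention-time grid: the modified-peptide trace
#' carries a Gaussian peak of area `occupancy * total_area`, the unmodified
#' trace one of area `(1 - occupancy) * total_area`. iid Gaussian noise is
#' added to each trace with standard deviation `noise_sigma` times that
#' trace's own apex height (electrospray XIC noise scales with signal); a
#' trace whose planted peak is absent (occupancy 0 or 1) receives pure noise
#' scaled to the partner trace's apex.
#'
#' @param occupancy Planted occupancy in `[0, 1]`.
#' @param total_area Total peptide signal (intensity x minutes).
#' @param rt_apex_mod,rt_apex_unmod Apex retention times (minutes).
#' @param peak_sd Chromatographic peak standard deviation (minutes).
#' @param noise_sigma Noise standard deviation as a fraction of the larger
#'   apex height (default 0.05).
#' @param rt_range,rt_step Grid specification (minutes).
#' @param seed Integer seed.
#' @return List: `modified`, `unmodified` ([chromatogram_trace()]s) and
#'   `truth` (planted occupancy and areas).
#' @export
gen_xic_pair <- function(occupancy, total_area = 1000,
                         rt_apex_mod = 12, rt_apex_unmod = 18,
                         peak_sd = 0.15, noise_sigma = 0.05,
                         rt_range = c(0, 30), rt_step = 0.02, seed = 1L) {
  stopifnot(occupancy >= 0, occupancy <= 1)
  withr_seed(seed)
  rt <- seq(rt_range[1], rt_range[2], by = rt_step)
  a_mod <- occupancy * total_area
  a_un <- (1 - occupancy) * total_area
  y_mod <- gaussian_trace(rt, a_mod, rt_apex_mod, peak_sd)
  y_un <- gaussian_trace(rt, a_un, rt_apex_unmod, peak_sd)
  if (noise_sigma > 0) {
    apex_mod <- max(y_mod); apex_un <- max(y_un)
    if (apex_mod == 0) apex_mod <- apex_un
    if (apex_un == 0) apex_un <- apex_mod
    y_mod <- y_mod + stats::rnorm(length(rt), 0, noise_sigma * apex_mod)
    y_un <- y_un + stats::rnorm(length(rt), 0, noise_sigma * apex_un)
  }
  list(
    modified = chromatogram_trace(rt, y_mod),
    unmodified = chromatogram_trace(rt, y_un),
    truth = list(occupancy = occupancy, area_mod = a_mod, area_unmod = a_un,
                 rt_apex_mod = rt_apex_mod, rt_apex_unmod = rt_apex_unmod,
                 seed = seed)
  )
}

#' Generate methylation-state counts from a proportional-odds model
#'
#' Per-replicate multinomial draws of size `effective_n` from
#' `P(Y <= j | strain) = plogis(cutpoints[j] - beta[strain])`.
#'
#' @param beta Named numeric vector of strain effects (include the reference
#'   at 0).
#' @param cutpoints Increasing numeric vector of 3 cutpoints.
#' @param n_replicates Replicates per strain.
#' @param effective_n Multinomial size per replicate.
#' @param seed Integer seed.
#' @return List: `counts` (strain, replicate, me0..me3) and `truth`.
#' @export
gen_methyl_counts <- function(beta, cutpoints = c(-0.4, 0.25, 1.1),
                              n_replicates = 3L, effective_n = 1000L,
                              seed = 1L) {
  if (is.unsorted(cutpoints, strictly = TRUE) || length(cutpoints) != 3L) {
    stop("cutpoints must be 3 strictly increasing values")
  }
  withr_seed(seed)
  rows <- list()
  for (s in names(beta)) {
    p <- po_probs(cutpoints, beta[[s]])
    for (r in seq_len(n_replicates)) {
      cnt <- as.integer(stats::rmultinom(1, effective_n, p))
      rows[[length(rows) + 1L]] <- data.frame(
        strain = s, replicate = r,
        me0 = cnt[1], me1 = cnt[2], me2 = cnt[3], me3 = cnt[4])
    }
  }
  list(counts = do.call(rbind, rows),
       truth = list(beta = beta, cutpoints = cutpoints,
                    effective_n = effective_n, seed = seed))
}

#' Generate evidence tables with planted network edges
#'
#' Planted edges receive evidence records that pass the admission rules
#' (motif score > 2 or significant perturbation fold-change of the correct
#' sign); noise records fail at least one rule. A planted genetic-only
#' record is included to exercise the genetic-admission rule.
#'
#' @param planted data.frame with `regulator`, `regulator_class`,
#'   `substrate`, `site`, `evidence_type` (one of `motif_prediction`,
#'   `quant_perturbation`, `physical_interaction`).
#' @param n_noise Number of noise records per evidence table.
#' @param genetic Optional data.frame (`regulator`, `substrate`) of genetic
#'   records (corroborating or not).
#' @param seed Integer seed.
#' @return List: `motif`, `quant`, `physical`, `genetic` tables and `truth`
#'   (the planted edge table).
#' @export
gen_evidence_tables <- function(planted, n_noise = 5L, genetic = NULL,
                                seed = 1L) {
  withr_seed(seed)
  motif <- planted[planted$evidence_type == "motif_prediction", , drop = FALSE]
  quant <- planted[planted$evidence_type == "quant_perturbation", , drop = FALSE]
  phys <- planted[planted$evidence_type == "physical_interaction", , drop = FALSE]
  motif$score <- if (nrow(motif) > 0L)
    round(stats::runif(nrow(motif), 2.5, 8), 2) else numeric(0)
  quant$p_value <- if (nrow(quant) > 0L)
    signif(stats::runif(nrow(quant), 1e-5, 0.04), 3) else numeric(0)
  quant$fold_change <- if (nrow(quant) > 0L)
    round(ifelse(quant$regulator_class == "kinase",
                 stats::runif(nrow(quant), -4, -1.6),
                 stats::runif(nrow(quant), 1.6, 4)), 2) else numeric(0)
  noise_reg <- function(n) sprintf("NOISE_KIN%d", seq_len(n))
  if (n_noise > 0L) {
    motif_noise <- data.frame(
      regulator = noise_reg(n_noise), regulator_class = "kinase",
      substrate = "NOISE_SUB", site = NA_character_, evidence_type = "motif_prediction",
      score = round(stats::runif(n_noise, 0, 2), 2))
    quant_noise <- data.frame(
      regulator = noise_reg(n_noise), regulator_class = "kinase",
      substrate = "NOISE_SUB", site = NA_character_,
      evidence_type = "quant_perturbation",
      p_value = signif(stats::runif(n_noise, 0.06, 0.9), 3),
      fold_change = round(stats::runif(n_noise, -4, 4), 2))
    motif <- rbind(motif, motif_noise[, names(motif), drop = FALSE])
    quant <- rbind(quant, quant_noise[, names(quant), drop = FALSE])
  }
  list(motif = motif, quant = quant, physical = phys,
       genetic = genetic, truth = planted)
}
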