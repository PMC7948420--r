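# Independent oracles used across the suite. These deliberately do not share
# code with the package internals they check.

# Residue masses recomputed from elemental composition and atomic
# monoisotopic masses, independent of the package's residue table.
oracle_residue_masses <- function() {
  atom <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
            O = 15.9949146221, S = 31.97207069)
  comp <- list(
    G = c(C = 2, H = 3, N = 1, O = 1), A = c(C = 3, H = 5, N = 1, O = 1),
    S = c(C = 3, H = 5, N = 1, O = 2), P = c(C = 5, H = 7, N = 1, O = 1),
    V = c(C = 5, H = 9, N = 1, O = 1), T = c(C = 4, H = 7, N = 1, O = 2),
    C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
    L = c(C = 6, H = 11, N = 1, O = 1), I = c(C = 6, H = 11, N = 1, O = 1),
    N = c(C = 4, H = 6, N = 2, O = 2), D = c(C = 4, H = 5, N = 1, O = 3),
    Q = c(C = 5, H = 8, N = 2, O = 2), K = c(C = 6, H = 12, N = 2, O = 1),
    E = c(C = 5, H = 7, N = 1, O = 3),
    M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
    H = c(C = 6, H = 7, N = 3, O = 1), F = c(C = 9, H = 9, N = 1, O = 1),
    R = c(C = 6, H = 12, N = 4, O = 1), Y = c(C = 9, H = 9, N = 1, O = 2),
    W = c(C = 11, H = 10, N = 2, O = 1)
  )
  vapply(comp, function(x) sum(atom[names(x)] * x), numeric(1))
}

oracle_peptide_mass <- function(sequence, mod_deltas = numeric()) {
  m <- oracle_residue_masses()
  water <- 2 * 1.0078250319 + 15.9949146221
  sum(m[strsplit(sequence, "")[[1]]]) + water + sum(mod_deltas)
}

# Brute-force free-end-gap aligner: enumerates every monotone alignment path
# (diagonal / up = residue of a vs gap / left = gap vs residue of b), scores
# each path with affine internal gap costs (open + len * extend) while the
# maximal leading and trailing gap runs are free, and returns the maximum.
oracle_align_score <- function(a, b, sub, gap_open = 12, gap_extend = 3) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  best <- -Inf
  # state: score so far; run = current gap move ("U"/"L") and its length;
  # leading = TRUE while the path is still its initial gap run (free)
  rec <- function(i, j, score, run_type, run_len, leading) {
    if (i == n && j == m) {
      # refund the trailing gap run unless it was the (already free) lead
      if (!is.na(run_type) && !leading && run_len > 0) {
        score <- score + gap_open + gap_extend * run_len
      }
      if (score > best) best <<- score
      return(invisible())
    }
    if (i < n && j < m) {
      rec(i + 1L, j + 1L, score + sub[ca[i + 1L], cb[j + 1L]],
          NA_character_, 0L, FALSE)
    }
    for (mv in c("U", "L")) {
      if (mv == "U" && i >= n) next
      if (mv == "L" && j >= m) next
      same <- !is.na(run_type) && run_type == mv
      lead2 <- leading && (is.na(run_type) || same)
      cost <- if (lead2) 0 else if (same) gap_extend else
        gap_open + gap_extend
      rec(i + (mv == "U"), j + (mv == "L"), score - cost,
          mv, if (same) run_len + 1L else 1L, lead2)
    }
  }
  rec(0L, 0L, 0, NA_character_, 0L, TRUE)
  best
}

# Minimal valid PSM row; override any field.
make_psm <- function(...) {
  base <- data.frame(
    protein_id = "P1", peptide = "AKSAPK", mods = "3:phospho",
    protease = "trypsin", fragmentation = "HCD",
    ion_score = 55, expect_p = 0.001, psm_fdr = 0.002, loc_prob = "3:99.5",
    retention_time = 20.5, precursor_mz = 500.25, charge = 2,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}
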