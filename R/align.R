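#' BLOSUM62 substitution matrix
#'
#' Convenience accessor for the BLOSUM62 matrix shipped with Biostrings.
#'
#' @return Integer substitution matrix over the amino-acid alphabet.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Global pairwise alignment with free end gaps
#'
#' Semi-global Needleman-Wunsch alignment: internal gaps incur an affine
#' penalty (a gap of length L costs `gap_open + L * gap_extend`), while gaps
#' at either end of either sequence are free. Ties in the dynamic program are
#' broken deterministically: diagonal (match/mismatch) is preferred, then
#' consuming a residue of `seq_a` against a gap, then a residue of `seq_b`.
#'
#' @param seq_a,seq_b Sequences to align (seq_a is the anchor whose positions
#'   are mapped).
#' @param sub Substitution matrix with both alphabets in its dimnames
#'   (default [blosum62()]).
#' @param gap_open Cost charged once per internal gap (default 12).
#' @param gap_extend Cost per gapped position of an internal gap (default 3).
#' @return List of class `alignment_result`: `aligned_a`, `aligned_b` (gapped
#'   strings), `score`, `map_ab` (integer vector over positions of `seq_a`;
#'   the aligned position in `seq_b`, or NA when aligned to a gap).
#' @export
align_free_end_gaps <- function(seq_a, seq_b, sub = blosum62(),
                                gap_open = 12, gap_extend = 3) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  if (length(a) == 0L || length(b) == 0L) stop("sequences must be non-empty")
  bad <- setdiff(c(a, b), rownames(sub))
  if (length(bad) > 0L) {
    stop("alphabet error: symbol(s) not in substitution matrix: ",
         paste(unique(bad), collapse = ", "))
  }
  n <- length(a); m <- length(b)
  NEG <- -1e9
  # Gotoh: M = end in match state, X = gap in b (consume a), Y = gap in a
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1, 1] <- 0
  # free leading gaps
  X[2:(n + 1L), 1] <- 0
  Y[1, 2:(m + 1L)] <- 0
  for (i in 2:(n + 1L)) {
    si <- sub[a[i - 1L], ]
    for (j in 2:(m + 1L)) {
      s <- si[b[j - 1L]]
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + s
      X[i, j] <- max(M[i - 1L, j] - gap_open - gap_extend,
                     X[i - 1L, j] - gap_extend,
                     Y[i - 1L, j] - gap_open - gap_extend)
      Y[i, j] <- max(M[i, j - 1L] - gap_open - gap_extend,
                     Y[i, j - 1L] - gap_extend,
                     X[i, j - 1L] - gap_open - gap_extend)
    }
  }
  # free trailing gaps: but trailing-gap states must not pay the internal
  # penalty, so recompute the best terminal cell over the last row/column
  # using the three states directly
  best <- function(i, j) max(M[i, j], X[i, j], Y[i, j])
  end_candidates <- rbind(
    cbind(i = n + 1L, j = 1:(m + 1L)),
    cbind(i = 1:(n + 1L), j = m + 1L)
  )
  scores <- apply(end_candidates, 1L, function(r) best(r[1], r[2]))
  # deterministic end choice: highest score, then largest i, then largest j
  o <- order(-scores, -end_candidates[, "i"], -end_candidates[, "j"])
  ei <- end_candidates[o[1], "i"]; ej <- end_candidates[o[1], "j"]
  score <- scores[o[1]]

  # traceback
  al_a <- character(); al_b <- character()
  # trailing free gaps
  if (ei <= n) {
    al_a <- rev(a[ei:n]); al_b <- rep("-", n - ei + 1L)
  } else if (ej <= m) {
    al_b <- rev(b[ej:m]); al_a <- rep("-", m - ej + 1L)
  }
  i <- ei; j <- ej
  state <- c("M", "X", "Y")[which.max(c(M[i, j], X[i, j], Y[i, j]))]
  tol <- 1e-9
  while (!(i == 1L && j == 1L)) {
    if (state == "M") {
      al_a <- c(al_a, a[i - 1L]); al_b <- c(al_b, b[j - 1L])
      prev <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      i <- i - 1L; j <- j - 1L
      if (i == 1L && j == 1L) break
      state <- c("M", "X", "Y")[which(abs(prev - max(prev)) < tol)[1]]
    } else if (state == "X") {
      al_a <- c(al_a, a[i - 1L]); al_b <- c(al_b, "-")
      cur <- X[i, j]
      if (j == 1L) {
        # free leading gap column
        i <- i - 1L
        state <- if (i == 1L) "M" else "X"
        if (i == 1L && j == 1L) break
        next
      }
      cand <- c(M = M[i - 1L, j] - gap_open - gap_extend,
                X = X[i - 1L, j] - gap_extend,
                Y = Y[i - 1L, j] - gap_open - gap_extend)
      i <- i - 1L
      state <- names(cand)[which(abs(cand - cur) < tol)[1]]
    } else {
      al_a <- c(al_a, "-"); al_b <- c(al_b, b[j - 1L])
      cur <- Y[i, j]
      if (i == 1L) {
        j <- j - 1L
        state <- if (j == 1L) "M" else "Y"
        if (i == 1L && j == 1L) break
        next
      }
      cand <- c(M = M[i, j - 1L] - gap_open - gap_extend,
                Y = Y[i, j - 1L] - gap_extend,
                X = X[i, j - 1L] - gap_open - gap_extend)
      j <- j - 1L
      state <- names(cand)[which(abs(cand - cur) < tol)[1]]
    }
  }
  aligned_a <- paste(rev(al_a), collapse = "")
  aligned_b <- paste(rev(al_b), collapse = "")
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  pa <- cumsum(ca != "-")
  pb <- cumsum(cb != "-")
  map_ab <- rep(NA_integer_, n)
  keep <- ca != "-" & cb != "-"
  map_ab[pa[keep]] <- pb[keep]
  structure(list(aligned_a = aligned_a, aligned_b = aligned_b,
                 score = score, map_ab = map_ab),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  cat("score:", x$score, "\n")
  invisible(x)
}

#' Classify phosphosite conservation across an ortholog alignment
#'
#' For each modified position on the anchor sequence: `not_aligned` when the
#' position faces a gap; `phosphosite_conserved` when the aligned partner
#' residue is S/T/Y and is itself a known phosphosite; `residue_conserved`
#' when the partner residue is S/T/Y but not a known site; otherwise
#' `not_conserved`.
#'
#' @param sites data.frame with a `position` column (positions on the anchor
#'   sequence of the alignment).
#' @param alignment An [align_free_end_gaps()] result (anchor = `seq_a`).
#' @param partner_seq Partner (e.g. human ortholog) sequence.
#' @param partner_phospho Integer positions of known phosphosites on the
#'   partner sequence.
#' @return The input `sites` with added `partner_position`,
#'   `partner_residue`, `conservation`.
#' @export
conserved_phosphosites <- function(sites, alignment, partner_seq,
                                   partner_phospho = integer()) {
  stopifnot(inherits(alignment, "alignment_result"))
  pb <- strsplit(partner_seq, "")[[1]]
  sites$partner_position <- alignment$map_ab[sites$position]
  sites$partner_residue <- ifelse(is.na(sites$partner_position), NA_character_,
                                  pb[sites$partner_position])
  sites$conservation <- ifelse(
    is.na(sites$partner_position), "not_aligned",
    ifelse(sites$partner_residue %in% c("S", "T", "Y"),
           ifelse(sites$partner_position %in% partner_phospho,
                  "phosphosite_conserved", "residue_conserved"),
           "not_conserved"))
  sites
}
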