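#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aas), sub("\\s.*$", "", names(aas)))
}

#' Write protein sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(sequences), filepath = path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a PSM data.frame back to the TSV schema
#'
#' Inverse of [read_psm_table()]: list columns `mods` and `loc_prob` are
#' collapsed to `position:value` strings.
#'
#' @param psms PSM data.frame (parsed or string columns).
#' @param path Output TSV.
#' @export
write_psm_table <- function(psms, path) {
  if (is.list(psms$mods) && !is.character(psms$mods)) {
    psms$mods <- vapply(psms$mods, function(m)
      if (nrow(m) == 0L) "" else
        paste(sprintf("%d:%s", m$position, m$value), collapse = ";"),
      character(1))
    psms$loc_prob <- vapply(psms$loc_prob, function(m)
      if (nrow(m) == 0L) "" else
        paste(sprintf("%d:%g", m$position, m$value), collapse = ";"),
      character(1))
  }
  write_tsv(psms, path)
}
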