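#' Published sequence lengths of reference chloroplast records
#'
#' Lengths (in nucleotides) of the EMBL records used as reference points
#' for the fragment-count arithmetic, read from the package's
#' \code{extdata/record_lengths.tsv}.  The fragment count of linear tiling
#' depends only on the record length, so these public metadata suffice to
#' check the tiling without the sequences themselves.
#'
#' @return named integer vector of record lengths, names are accessions.
#' @export
knownRecordLengths <- function() {
  path <- system.file("extdata", "record_lengths.tsv",
                      package = "tripletPhase", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  setNames(as.integer(df$length_nt), df$accession)
}
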