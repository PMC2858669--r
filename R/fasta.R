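# FASTA input/output. Parsing is delegated to Biostrings; this layer adds
# id/label extraction, alphabet validation and duplicate detection.

#' Read protein sequences from a FASTA file
#'
#' The token before the first whitespace in each header becomes the record
#' id; any remaining header text becomes the class label (default
#' `"unknown"`). Sequences are upper-cased and whitespace-stripped; records
#' containing symbols outside the 20 standard residues are rejected with a
#' diagnostic naming the offending symbol. Ambiguity codes (B, Z, X, U, O)
#' can instead be dropped residue-wise with a warning.
#'
#' @param path Path to a FASTA file.
#' @param ambiguity `"error"` (default) or `"drop"`; see
#'   [normalize_sequence()].
#' @return A tibble with columns `id`, `label`, `sequence`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a cargo", "ACDK", ">b", "KRLI"), f)
#' read_fasta(f)
read_fasta <- function(path, ambiguity = c("error", "drop")) {
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  id <- stringr::str_extract(headers, "^\\S+")
  rest <- stringr::str_trim(stringr::str_remove(headers, "^\\S+"))
  label <- ifelse(nchar(rest) > 0, rest, "unknown")
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    abort(sprintf("duplicate FASTA id(s): %s", paste(dup, collapse = ", ")))
  }
  sequence <- normalize_sequence(as.character(set), id = id, ambiguity = ambiguity)
  tibble::tibble(id = id, label = label, sequence = unname(sequence))
}

#' Write protein sequences to a FASTA file
#'
#' Headers are `id` followed by `label` when the label is informative
#' (not `"unknown"`), so that [read_fasta()] round-trips ids, labels and
#' sequences exactly.
#'
#' @param proteins A data frame with columns `id`, `sequence` and
#'   optionally `label`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  proteins <- check_proteins(proteins)
  header <- ifelse(
    proteins$label == "unknown",
    proteins$id,
    paste(proteins$id, proteins$label)
  )
  set <- Biostrings::AAStringSet(setNames(proteins$sequence, header))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
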