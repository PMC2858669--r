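# Internal constants and validators shared across the package.

# The 20 standard one-letter residue codes, alphabetical.
AMINO_ACIDS <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Ambiguity / non-standard codes that may appear in real FASTA files.
AMBIGUITY_CODES <- c("B", "Z", "X", "U", "O")

# Average residue masses in Da (residue = amino acid minus one water).
RESIDUE_MASS <- c(
  A = 71.0788,  C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519,  H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167,  Q = 128.1307, R = 156.1875,
  S = 87.0782,  T = 101.1051, V = 99.1326,  W = 186.2132, Y = 163.1760
)
WATER_MASS <- 18.0153

#' Normalize and validate a protein sequence
#'
#' Upper-cases, strips whitespace, and checks that only the 20 standard
#' residue codes remain. Ambiguity codes (B, Z, X, U, O) can optionally be
#' dropped with a warning; any other symbol is always an error.
#'
#' @param sequence Character vector of amino-acid sequences.
#' @param id Optional ids used in diagnostics (recycled).
#' @param ambiguity Either `"error"` (default) or `"drop"`: drop removes
#'   ambiguity-code residues with a warning instead of failing.
#' @return The normalized character vector.
#' @export
normalize_sequence <- function(sequence, id = NULL,
                               ambiguity = c("error", "drop")) {
  ambiguity <- match.arg(ambiguity)
  stopifnot(is.character(sequence))
  id <- id %||% as.character(seq_along(sequence))
  seqs <- toupper(gsub("[[:space:]]+", "", sequence))
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "")[[1]]
    bad <- setdiff(unique(chars), AMINO_ACIDS)
    amb <- intersect(bad, AMBIGUITY_CODES)
    if (length(amb) > 0 && ambiguity == "drop") {
      warn(sprintf(
        "dropping ambiguity residue(s) %s from sequence '%s'",
        paste(amb, collapse = ", "), id[[i]]
      ))
      chars <- chars[!chars %in% amb]
      seqs[[i]] <- paste(chars, collapse = "")
      bad <- setdiff(bad, amb)
    }
    if (length(bad) > 0) {
      abort(sprintf(
        "invalid residue symbol(s) %s in sequence '%s'",
        paste(sprintf("'%s'", bad), collapse = ", "), id[[i]]
      ))
    }
    if (nchar(seqs[[i]]) == 0) {
      abort(sprintf("sequence '%s' is empty after normalization", id[[i]]))
    }
  }
  seqs
}

# residue count matrix: one row per sequence, 20 columns in AMINO_ACIDS order
residue_counts <- function(sequence) {
  mat <- vapply(
    AMINO_ACIDS,
    function(a) stringr::str_count(sequence, stringr::fixed(a)),
    numeric(length(sequence))
  )
  if (length(sequence) == 1L) mat <- matrix(mat, nrow = 1, dimnames = list(NULL, AMINO_ACIDS))
  mat
}

#' Molecular weight of a protein sequence
#'
#' Sum of average residue masses plus one water, in Daltons.
#'
#' @param sequence Character vector of amino-acid sequences.
#' @return Numeric vector of masses in Da.
#' @export
#' @examples
#' molecular_weight("ACDEFG")
molecular_weight <- function(sequence) {
  sequence <- normalize_sequence(sequence)
  counts <- residue_counts(sequence)
  drop(counts %*% RESIDUE_MASS[AMINO_ACIDS]) + WATER_MASS
}

# shared input check: a proteins table with id/sequence (label optional)
check_proteins <- function(proteins, arg = "proteins") {
  if (!is.data.frame(proteins) ||
      !all(c("id", "sequence") %in% names(proteins))) {
    abort(sprintf("`%s` must be a data frame with columns 'id' and 'sequence'", arg))
  }
  if (anyDuplicated(proteins$id)) {
    dup <- unique(proteins$id[duplicated(proteins$id)])
    abort(sprintf("duplicate protein id(s): %s", paste(dup, collapse = ", ")))
  }
  if (!"label" %in% names(proteins)) proteins$label <- "unknown"
  tibble::as_tibble(proteins)
}
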