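# Complex manifests: which chains (and how many copies of each) make up a
# receptor-cargo complex. A manifest is a tibble (complex, member, copies)
# whose members must resolve against a loaded protein table.

#' Build a complex manifest
#'
#' @param complex Character vector of complex names (one per member row).
#' @param member Character vector of member protein ids.
#' @param copies Integer copy counts (default 1, recycled).
#' @param proteins Protein table against which member ids are resolved.
#' @return A tibble with columns `complex`, `member`, `copies`.
#' @export
#' @examples
#' prots <- tibble::tibble(id = c("a", "b"), sequence = c("ACD", "KR"))
#' complex_manifest(c("c1", "c1"), c("a", "b"), proteins = prots)
complex_manifest <- function(complex, member, copies = 1L, proteins) {
  manifest <- tibble::tibble(
    complex = as.character(complex),
    member = as.character(member),
    copies = as.integer(copies)
  )
  validate_manifest(manifest, proteins)
}

#' Read a complex manifest from a tab-separated file
#'
#' Expected columns: `complex`, `member`, `copies` (copies optional,
#' default 1). Every member id must resolve to a row of `proteins`.
#'
#' @param path Path to the TSV manifest.
#' @param proteins Protein table (e.g. from [read_fasta()]).
#' @return A validated manifest tibble.
#' @export
read_complex_manifest <- function(path, proteins) {
  if (!file.exists(path)) abort(sprintf("manifest file not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("complex", "member") %in% names(df))) {
    abort("manifest must have columns 'complex' and 'member' (and optionally 'copies')")
  }
  if (!"copies" %in% names(df)) df$copies <- 1L
  validate_manifest(df[, c("complex", "member", "copies")], proteins)
}

validate_manifest <- function(manifest, proteins) {
  proteins <- check_proteins(proteins)
  manifest <- tibble::as_tibble(manifest)
  if (any(is.na(manifest$copies)) || any(manifest$copies < 1)) {
    abort("copy counts must be integers >= 1")
  }
  unknown <- setdiff(manifest$member, proteins$id)
  if (length(unknown) > 0) {
    abort(sprintf(
      "manifest member id(s) not found among loaded proteins: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  if (nrow(manifest) == 0) abort("manifest is empty")
  manifest
}
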