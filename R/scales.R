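# Residue-scale registry: named per-residue property scales with a
# category (hydrophobicity / polarity / other). The default registry is
# assembled from the published AAindex database (shipped with seqinr):
# 27 curated empirical hydrophobicity scales plus the Grantham (1974)
# polarity scale. A tab-separated registry file is the override path.

# curated AAindex accessions for the default hydrophobicity panel
HYDROPHOBICITY_ACCESSIONS <- c(
  "ARGP820101", # Argos et al. 1982, membrane-buried preference
  "CIDH920101", "CIDH920102", "CIDH920103", "CIDH920104", "CIDH920105", # Cid 1992
  "EISD840101", # Eisenberg consensus 1984
  "FAUJ830101", # Fauchere-Pliska pi 1983
  "GOLD730101", # Goldsack-Chalifoux 1973
  "JOND750101", # Jones 1975
  "JURD980101", # Juretic 1998 (modified Kyte-Doolittle)
  "KYTJ820101", # Kyte-Doolittle hydropathy 1982
  "LEVM760101", # Levitt 1976
  "MANP780101", # Manavalan-Ponnuswamy 1978
  "PONP800101", "PONP800102", "PONP800103", # Ponnuswamy 1980
  "PONP800104", "PONP800105", "PONP800106",
  "PONP930101", # Ponnuswamy 1993
  "PRAM900101", # Prabhakaran 1990
  "SWER830101", # Sweet-Eisenberg optimal matching 1983
  "WILM950101", "WILM950102", # Wilce 1995 RP-HPLC C18 / C8
  "WOLR790101", # Wolfenden 1979
  "ZIMJ680101"  # Zimmerman 1968
)
POLARITY_ACCESSION <- "GRAR740102" # Grantham 1974 polarity

aaindex_values <- function(accession) {
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  idx <- env$aaindex
  missing <- setdiff(accession, names(idx))
  if (length(missing) > 0) {
    abort(sprintf("AAindex accession(s) not found: %s", paste(missing, collapse = ", ")))
  }
  purrr::map(idx[accession], function(entry) {
    v <- entry$I
    names(v) <- vapply(names(v), function(nm) seqinr::a(nm), character(1))
    list(values = v[AMINO_ACIDS], description = entry$D)
  })
}

new_registry <- function(df) {
  stopifnot(all(c("scale", "category", AMINO_ACIDS) %in% names(df)))
  if (anyDuplicated(df$scale)) {
    dup <- unique(df$scale[duplicated(df$scale)])
    abort(sprintf("duplicate scale name(s): %s", paste(dup, collapse = ", ")))
  }
  bad <- !df$category %in% c("hydrophobicity", "polarity", "other")
  if (any(bad)) {
    abort(sprintf(
      "invalid category for scale(s): %s (must be hydrophobicity, polarity or other)",
      paste(df$scale[bad], collapse = ", ")
    ))
  }
  for (i in seq_len(nrow(df))) {
    vals <- unlist(df[i, AMINO_ACIDS])
    if (any(is.na(vals)) || !is.numeric(vals)) {
      missing <- AMINO_ACIDS[is.na(vals)]
      abort(sprintf(
        "scale '%s' is missing value(s) for residue(s): %s",
        df$scale[[i]], paste(missing, collapse = ", ")
      ))
    }
  }
  structure(tibble::as_tibble(df), class = c("scale_registry", class(tibble::tibble())))
}

#' Default residue-scale registry
#'
#' Builds the bundled registry: 27 curated empirical hydrophobicity scales
#' (Kyte-Doolittle, Eisenberg consensus, Fauchere-Pliska, the Cid,
#' Ponnuswamy and Wilce panels, and others) drawn from the AAindex
#' database, plus the Grantham polarity scale. Scale names are AAindex
#' accessions; a `description` column carries the human-readable name.
#'
#' @return A `scale_registry` tibble with columns `scale`, `category`,
#'   `description` and one column per residue.
#' @export
#' @examples
#' reg <- default_scales()
#' table(reg$category)
default_scales <- function() {
  acc <- c(HYDROPHOBICITY_ACCESSIONS, POLARITY_ACCESSION)
  entries <- aaindex_values(acc)
  df <- purrr::imap(entries, function(entry, name) {
    tibble::tibble(
      scale = name,
      category = if (name == POLARITY_ACCESSION) "polarity" else "hydrophobicity",
      description = entry$description,
      !!!as.list(entry$values)
    )
  })
  new_registry(dplyr::bind_rows(df))
}

#' Read a residue-scale registry from a tab-separated file
#'
#' Expected columns: `scale`, `category`, optionally `description`, and
#' one column per standard residue (A..Y). Every scale must define all 20
#' residues; missing values, duplicate names and unknown categories are
#' errors naming the offending scale.
#'
#' @param path Path to the TSV registry file.
#' @return A `scale_registry` tibble.
#' @export
read_scale_registry <- function(path) {
  if (!file.exists(path)) abort(sprintf("registry file not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE)
  missing_cols <- setdiff(c("scale", "category", AMINO_ACIDS), names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("registry is missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  new_registry(df)
}

#' Write a residue-scale registry to a tab-separated file
#'
#' @param registry A `scale_registry` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scale_registry <- function(registry, path) {
  readr::write_tsv(registry, path)
  invisible(path)
}

#' Extract one scale's residue values from a registry
#'
#' @param registry A `scale_registry` tibble.
#' @param name Scale name.
#' @return Named numeric vector over the 20 residues.
#' @export
scale_values <- function(registry, name) {
  row <- registry[registry$scale == name, , drop = FALSE]
  if (nrow(row) == 0) abort(sprintf("scale '%s' not found in registry", name))
  unlist(row[1, AMINO_ACIDS])
}

# scales x residues numeric matrix, rows named by scale
registry_matrix <- function(registry) {
  m <- as.matrix(registry[, AMINO_ACIDS])
  rownames(m) <- registry$scale
  m
}
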