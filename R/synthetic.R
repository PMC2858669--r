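# Synthetic protein cohorts with the compositional structure the analysis
# assumes: receptor-like chains (acidic + hydrophobic, importin-beta
# sized), cargo-like chains (lysine/arginine rich), FG-nucleoporin-like
# domains (short hydrophobic FG motifs separated by lysine-rich
# hydrophilic spacers) and proteome-background chains. Only composition
# statistics are emulated — nothing here is meant to fold.

# Swiss-Prot average amino-acid frequencies (%), the proteome background
BACKGROUND_FREQ <- c(
  A = 8.25, C = 1.38, D = 5.45, E = 6.72, F = 3.86,
  G = 7.07, H = 2.27, I = 5.91, K = 5.80, L = 9.65,
  M = 2.41, N = 4.06, P = 4.74, Q = 3.93, R = 5.53,
  S = 6.65, T = 5.36, V = 6.86, W = 1.10, Y = 2.92
)

RECEPTOR_BOOST_RESIDUES <- c("D", "E", "L", "I", "F", "V")
CARGO_BOOST_RESIDUES <- c("K", "R")
SPACER_BOOST_RESIDUES <- c("K", "S", "N", "T")

boost_freq <- function(freq, residues, factor) {
  freq[residues] <- freq[residues] * factor
  freq / sum(freq)
}

#' Residue composition profile for a synthetic class
#'
#' Preset classes: `background` (proteome-average frequencies, log-normal
#' lengths with median 450), `receptor_like` (D/E and hydrophobic
#' residues boosted 1.6x, median length 1000 to emulate
#' importin-beta-family size), `cargo_like` (K/R boosted 1.6x),
#' `fg_nup_like` (spacer-style composition: K/S/N/T enriched 2x with
#' acidic and hydrophobic residues halved; sequences from this class are
#' built by [generate_fg_domain()] with explicit FG motifs).
#'
#' @param class One of the four preset class names.
#' @param boost Enrichment factor for the receptor/cargo presets
#'   (default 1.6).
#' @return A `composition_profile`: class name, residue `frequencies`
#'   (sum 1), log-normal length parameters (`length_median`,
#'   `length_sdlog`).
#' @export
#' @examples
#' composition_profile("receptor_like")
composition_profile <- function(class = c("background", "receptor_like",
                                          "cargo_like", "fg_nup_like"),
                                boost = 1.6) {
  class <- match.arg(class)
  base <- BACKGROUND_FREQ / sum(BACKGROUND_FREQ)
  freq <- switch(class,
    background = base,
    receptor_like = boost_freq(base, RECEPTOR_BOOST_RESIDUES, boost),
    cargo_like = boost_freq(base, CARGO_BOOST_RESIDUES, boost),
    fg_nup_like = boost_freq(
      boost_freq(base, SPACER_BOOST_RESIDUES, 2),
      c("D", "E", "L", "I", "F", "V", "W", "M"), 0.5
    )
  )
  structure(
    list(
      class = class,
      frequencies = freq[AMINO_ACIDS],
      length_median = if (class == "receptor_like") 1000 else
        if (class == "fg_nup_like") 600 else 450,
      length_sdlog = 0.3
    ),
    class = "composition_profile"
  )
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("<composition_profile> %s, median length %g\n",
              x$class, x$length_median))
  invisible(x)
}

draw_length <- function(profile, n = 1L) {
  len <- round(rlnorm(n, meanlog = log(profile$length_median),
                      sdlog = profile$length_sdlog))
  pmax(len, 20L)
}

#' Sample one i.i.d. sequence from a composition profile
#'
#' Residues are drawn independently from the profile's frequency vector.
#' Uses the current RNG stream: wrap in [withr::with_seed()] (or set a
#' seed) for reproducibility.
#'
#' @param profile A [composition_profile()].
#' @param length Sequence length (>= 1); when `NULL`, drawn from the
#'   profile's log-normal length distribution (floored at 20).
#' @param id Record id.
#' @return A one-row tibble (`id`, `label`, `sequence`).
#' @export
sample_sequence <- function(profile, length = NULL, id = "synthetic") {
  stopifnot(inherits(profile, "composition_profile"))
  length <- length %||% draw_length(profile)
  if (length < 1) abort("sequence length must be >= 1")
  seq <- paste(
    sample(AMINO_ACIDS, size = length, replace = TRUE,
           prob = profile$frequencies),
    collapse = ""
  )
  tibble::tibble(id = id, label = profile$class, sequence = seq)
}

# spacer residue pool: profile frequencies with motif-forming residues
# removed, so spacers can never create extra motif occurrences
spacer_pool <- function(profile, exclude) {
  freq <- profile$frequencies
  freq <- freq[setdiff(names(freq), exclude)]
  freq / sum(freq)
}

#' Generate an FG-nucleoporin-like domain
#'
#' Alternating construction: `n_repeats` copies of the motif (`FxFG` with
#' x drawn from the spacer pool, or `GLFG`) separated by hydrophilic
#' spacers sampled from `spacer_profile` (default the `fg_nup_like`
#' preset, whose lysine enrichment makes the domain net positive at
#' pH 7.2). Spacers exclude phenylalanine (and, for FxFG, the variable
#' position excludes F and G), so the motif count is exact by
#' construction. Uses the current RNG stream.
#'
#' @param n_repeats Number of FG motifs (>= 1).
#' @param motif `"FxFG"` or `"GLFG"`.
#' @param spacer_profile A [composition_profile()] for the spacers.
#' @param spacer_length_mean Mean (Poisson) spacer length (default 12;
#'   0 concatenates the motifs).
#' @param id Record id.
#' @return A one-row tibble (`id`, `label = "fg_domain"`, `sequence`).
#' @export
#' @examples
#' withr::with_seed(1, generate_fg_domain(3, "GLFG"))
generate_fg_domain <- function(n_repeats, motif = c("FxFG", "GLFG"),
                               spacer_profile = composition_profile("fg_nup_like"),
                               spacer_length_mean = 12, id = "fg_domain") {
  motif <- match.arg(motif)
  if (n_repeats < 1) abort("n_repeats must be >= 1")
  if (spacer_length_mean < 0) abort("spacer_length_mean must be >= 0")
  pool <- spacer_pool(spacer_profile, "F")
  x_pool <- spacer_pool(spacer_profile, c("F", "G"))
  spacer <- function() {
    n <- stats::rpois(1, spacer_length_mean)
    if (n == 0) return("")
    paste(sample(names(pool), n, replace = TRUE, prob = pool), collapse = "")
  }
  motif_once <- function() {
    if (motif == "GLFG") return("GLFG")
    x <- sample(names(x_pool), 1, prob = x_pool)
    paste0("F", x, "FG")
  }
  parts <- character(2 * n_repeats - 1)
  for (i in seq_len(n_repeats)) {
    parts[2 * i - 1] <- motif_once()
    if (i < n_repeats) parts[2 * i] <- spacer()
  }
  tibble::tibble(id = id, label = "fg_domain", sequence = paste(parts, collapse = ""))
}

#' Generate a labelled synthetic cohort
#'
#' Draws `counts[class]` sequences per class, reproducibly from `seed`.
#' Receptor-, cargo- and background-class chains are i.i.d. samples from
#' their composition profiles; `fg_nup_like` chains are built by
#' [generate_fg_domain()] with a number of repeats matched to the drawn
#' target length. Optionally writes a FASTA file and a tab-separated
#' label table.
#'
#' @param counts Named integer vector with entries `receptor_like`,
#'   `cargo_like`, `fg_nup_like`, `background` (missing entries are 0).
#' @param seed Integer seed; generation is a pure function of
#'   `(counts, seed, boost)`.
#' @param boost Enrichment factor passed to [composition_profile()].
#' @param fasta,labels Optional output paths (FASTA / TSV).
#' @return A tibble (`id`, `label`, `class`, `sequence`) with attributes
#'   `seed` and `counts`.
#' @export
#' @examples
#' cohort <- generate_cohort(c(receptor_like = 3, cargo_like = 3), seed = 1)
generate_cohort <- function(counts = c(receptor_like = 10, cargo_like = 10,
                                       fg_nup_like = 10, background = 100),
                            seed = 1, boost = 1.6,
                            fasta = NULL, labels = NULL) {
  classes <- c("receptor_like", "cargo_like", "fg_nup_like", "background")
  n <- setNames(rep(0L, length(classes)), classes)
  if (is.null(names(counts)) || !all(names(counts) %in% classes)) {
    abort(sprintf("counts must be named from: %s", paste(classes, collapse = ", ")))
  }
  n[names(counts)] <- as.integer(counts)
  if (any(n < 0)) abort("counts must be >= 0")
  label_map <- c(receptor_like = "importin", cargo_like = "cargo",
                 fg_nup_like = "fg_domain", background = "background")

  cohort <- withr::with_seed(seed, {
    rows <- purrr::map(classes, function(cls) {
      if (n[[cls]] == 0) return(NULL)
      profile <- composition_profile(cls, boost = boost)
      purrr::map(seq_len(n[[cls]]), function(i) {
        id <- sprintf("%s_%03d", cls, i)
        rec <- if (cls == "fg_nup_like") {
          target_len <- draw_length(profile)
          # motif (4 aa) + mean spacer (12 aa) per repeat
          generate_fg_domain(max(3L, round(target_len / 16)),
                             motif = if (i %% 2 == 0) "GLFG" else "FxFG",
                             spacer_profile = profile, id = id)
        } else {
          sample_sequence(profile, id = id)
        }
        rec$label <- label_map[[cls]]
        rec$class <- cls
        rec
      })
    })
    dplyr::bind_rows(rows)
  })
  cohort <- cohort[, c("id", "label", "class", "sequence")]
  attr(cohort, "seed") <- seed
  attr(cohort, "counts") <- n
  if (!is.null(fasta)) write_fasta(cohort, fasta)
  if (!is.null(labels)) {
    readr::write_tsv(cohort[, c("id", "label", "class")], labels)
  }
  cohort
}
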