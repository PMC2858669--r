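# Ionization model and net charge at fixed pH.
#
# The net charge of a protein is the Henderson-Hasselbalch sum over every
# ionizable group occurrence: each basic group (H, K, R and the amino
# terminus) contributes +1/(1 + 10^(pH - pKa)) and each acidic group
# (C, D, E, Y and the carboxyl terminus) contributes -1/(1 + 10^(pKa - pH)).
# Each chain carries exactly one amino and one carboxyl terminus.

# default pK values match the EMBOSS iep defaults
DEFAULT_PKA <- c(
  Nterm = 8.6, Cterm = 3.6,
  C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1
)
GROUP_SIGN <- c(
  Nterm = +1, Cterm = -1,
  C = -1, D = -1, E = -1, H = +1, K = +1, R = +1, Y = -1
)

#' Ionization model: pKa values and signs of ionizable groups
#'
#' Holds the pKa of the seven ionizable side chains (C, D, E, H, K, R, Y)
#' and the two chain termini, together with their charge signs. Acidic
#' groups (D, E, C, Y, carboxyl terminus) carry sign -1; basic groups
#' (H, K, R, amino terminus) carry sign +1. Histidine is included as a
#' basic group and therefore contributes fractionally near neutral pH.
#'
#' @param pKa Named numeric vector of pKa overrides; names from
#'   `c("Nterm","Cterm","C","D","E","H","K","R","Y")`. Unnamed groups keep
#'   their defaults (amino terminus 8.6, carboxyl terminus 3.6, C 8.5,
#'   D 3.9, E 4.1, H 6.5, K 10.8, R 12.5, Y 10.1).
#' @return An object of class `ionization_model`: a list with numeric
#'   vectors `pKa` and `sign`.
#' @export
#' @examples
#' ionization_model()
#' ionization_model(pKa = c(H = 6.0))
ionization_model <- function(pKa = NULL) {
  values <- DEFAULT_PKA
  if (!is.null(pKa)) {
    if (is.null(names(pKa)) || !all(names(pKa) %in% names(DEFAULT_PKA))) {
      abort(sprintf(
        "pKa overrides must be named from: %s",
        paste(names(DEFAULT_PKA), collapse = ", ")
      ))
    }
    values[names(pKa)] <- pKa
  }
  if (any(values <= 0 | values >= 14)) {
    abort("all pKa values must lie in (0, 14)")
  }
  structure(
    list(pKa = values, sign = GROUP_SIGN[names(values)]),
    class = "ionization_model"
  )
}

#' @export
print.ionization_model <- function(x, ...) {
  cat("<ionization_model>\n")
  print(round(x$pKa, 2))
  invisible(x)
}

#' Read ionization / pH configuration from YAML or JSON
#'
#' The file may contain a `pKa:` mapping (group -> value) and a `pH:`
#' scalar. Returns a list with elements `ionization` (an
#' [ionization_model()]) and `pH` (default 7.2 when absent).
#'
#' @param path Path to a YAML (or JSON, which YAML subsumes) file.
#' @return List with `ionization` and `pH`.
#' @export
read_ionization_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  pKa <- if (!is.null(cfg$pKa)) unlist(cfg$pKa) else NULL
  list(
    ionization = ionization_model(pKa = pKa),
    pH = cfg$pH %||% 7.2
  )
}

# fractional charge of each group at pH, for a pKa/sign pair:
#   basic:  +1/(1 + 10^(pH - pKa));  acidic: -1/(1 + 10^(pKa - pH))
group_fraction <- function(pH, pKa, sign) {
  sign / (1 + 10^(sign * (pH - pKa)))
}

# counts of ionizable groups per sequence (rows) incl. one of each terminus
ionizable_counts <- function(sequence, ionization) {
  counts <- residue_counts(sequence)
  side <- setdiff(names(ionization$pKa), c("Nterm", "Cterm"))
  mat <- cbind(
    Nterm = rep(1, length(sequence)),
    Cterm = rep(1, length(sequence)),
    counts[, side, drop = FALSE]
  )
  mat[, names(ionization$pKa), drop = FALSE]
}

# charge at (possibly per-row) pH given a precomputed ionizable count matrix
charge_from_counts <- function(counts, pH, ionization) {
  groups <- names(ionization$pKa)
  frac <- vapply(
    groups,
    function(g) group_fraction(pH, ionization$pKa[[g]], ionization$sign[[g]]),
    numeric(length(pH))
  )
  if (length(pH) == 1L) frac <- matrix(frac, nrow = 1, dimnames = list(NULL, groups))
  rowSums(counts * frac)
}

#' Net charge of a protein at fixed pH
#'
#' Henderson-Hasselbalch sum over every ionizable residue occurrence plus
#' one amino and one carboxyl terminus, in elementary-charge units (e).
#' The default pH of 7.2 is the intracellular pH at which translocation
#' through the nuclear pore is modelled.
#'
#' @param sequence Character vector of amino-acid sequences.
#' @param pH pH at which to evaluate the charge (scalar in (0, 14)).
#' @param ionization An [ionization_model()].
#' @return Numeric vector of net charges in e.
#' @export
#' @examples
#' net_charge("GG")                  # two termini only, ~ -0.038 e
#' net_charge(c("KKK", "DDD"))
net_charge <- function(sequence, pH = 7.2, ionization = ionization_model()) {
  if (!is.numeric(pH) || length(pH) != 1L || pH <= 0 || pH >= 14) {
    abort("`pH` must be a single number in (0, 14)")
  }
  sequence <- normalize_sequence(sequence)
  counts <- ionizable_counts(sequence, ionization)
  unname(charge_from_counts(counts, rep(pH, nrow(counts)), ionization))
}

# vectorized bisection: find pH root of each row's charge curve.
# net charge is strictly decreasing in pH, so the root is unique. A fixed
# iteration count (interval 14/2^60 ~ 1e-17 pH units, far below any
# useful tolerance) keeps the result independent of how rows are batched.
bisect_pI <- function(counts, ionization, tolerance = 1e-6, iterations = 60L) {
  n <- nrow(counts)
  lo <- rep(0, n)
  hi <- rep(14, n)
  mid <- rep(7, n)
  for (i in seq_len(iterations)) {
    mid <- (lo + hi) / 2
    q <- charge_from_counts(counts, mid, ionization)
    pos <- q > 0 # charge positive -> root is at higher pH
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  mid
}

#' Isoelectric point of a protein
#'
#' The pH at which the net charge is zero, found by bisection on the
#' interval (0, 14). The charge curve is strictly decreasing in pH (every
#' group's fractional charge is), so the root is unique; the termini
#' guarantee at least one acidic and one basic group.
#'
#' @inheritParams net_charge
#' @param tolerance Convergence tolerance on |charge| in e (default 1e-6).
#' @return Numeric vector of isoelectric points in pH units.
#' @export
#' @examples
#' isoelectric_point("GG")   # midpoint of the terminus pKas, 6.1
isoelectric_point <- function(sequence, ionization = ionization_model(),
                              tolerance = 1e-6) {
  sequence <- normalize_sequence(sequence)
  counts <- ionizable_counts(sequence, ionization)
  unname(bisect_pI(counts, ionization, tolerance))
}
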