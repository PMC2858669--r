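# Independent oracles used across the suite. These re-derive quantities
# by the most literal route possible (per-residue loops, longhand
# constants) and stay independent of the package internals they check.

# Henderson-Hasselbalch net charge by explicit loop over every residue
# occurrence plus the two termini.
brute_force_charge <- function(sequence, pH = 7.2) {
  pka <- c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
           H = 6.5, K = 10.8, R = 12.5, Y = 10.1)
  basic <- c("Nterm", "H", "K", "R")
  groups <- c("Nterm", "Cterm", strsplit(sequence, "")[[1]])
  q <- 0
  for (g in groups) {
    if (!g %in% names(pka)) next
    q <- q + if (g %in% basic) {
      1 / (1 + 10^(pH - pka[[g]]))
    } else {
      -1 / (1 + 10^(pka[[g]] - pH))
    }
  }
  q
}

random_sequence <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# tiny three-scale registry written from first principles (Kyte-Doolittle
# values typed in directly), for registry-format tests
tiny_registry_tibble <- function() {
  kd <- c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
          H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
          P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
          W = -0.9, Y = -1.3)
  values <- as.data.frame(rbind(kd, -kd, abs(kd)))
  tibble::as_tibble(cbind(
    data.frame(
      scale = c("kd", "kd_flipped", "grantham_polarity"),
      category = c("hydrophobicity", "hydrophobicity", "polarity")
    ),
    values
  ))
}
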