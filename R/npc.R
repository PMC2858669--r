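# Screened-Coulomb model of the electrostatic contribution to NPC
# translocation. The pore is a cylinder lined by FG-nucleoporins whose
# charge, within one screening length of the particle surface, interacts
# with the particle's net charge Q_NTR. In Debye-Hueckel form the
# interaction of the two effective charges separated by the screening
# length lambda is
#
#   E / kBT = Q_NTR * Q_NPC * e^2 / (4 pi eps0 epsilon lambda kB T)
#
# with epsilon the dielectric of water. Q_NPC is the expected nucleoporin
# charge inside a hemisphere of radius lambda at the particle surface:
# with N nucleoporins of median charge q in a pore of volume V, the
# uniform-density expectation is N * q * (2/3 pi lambda^3) / V.

# CODATA 2018 constants
E_CHARGE <- 1.602176634e-19  # C
EPSILON0 <- 8.8541878128e-12 # F/m
K_BOLTZ  <- 1.380649e-23     # J/K

#' NPC model parameters
#'
#' Pore geometry, FG-nucleoporin census and charge, screening length,
#' dielectric and temperature. Defaults describe the yeast NPC: a
#' cylinder of radius 19 nm and height 37 nm holding 13 FG-nucleoporin
#' species at the conservative copy number of 8, in water (dielectric 80)
#' with a cytoplasmic screening length of 1 nm at 298.15 K.
#'
#' The local barrier charge `q_npc` can be supplied three ways, in order
#' of precedence: directly (`q_npc`, default 0.07 e, the census-based
#' estimate at these defaults), via a `median_charge` for the
#' nucleoporins, or via the full vector of `nup_charges` (whose median is
#' used). See [local_npc_charge()].
#'
#' @param radius_nm,height_nm Pore cylinder radius and height (nm).
#' @param species Number of FG-nucleoporin species (13).
#' @param copies Copies per species; 8 (conservative) or 16.
#' @param q_npc Local barrier charge in e, or `NULL` to derive it from
#'   the census and median charge.
#' @param median_charge Median net charge of one FG-nucleoporin (e).
#' @param nup_charges Optional numeric vector of per-nucleoporin charges
#'   (e); its median is used when `median_charge` is absent.
#' @param lambda_nm Screening length (nm, default 1).
#' @param epsilon Relative dielectric constant (default 80, water).
#' @param temperature_k Temperature (K, default 298.15).
#' @return An `npc_model` object (a validated list).
#' @export
#' @examples
#' npc_model()
#' npc_model(q_npc = NULL, median_charge = 10)
npc_model <- function(radius_nm = 19, height_nm = 37,
                      species = 13L, copies = 8L,
                      q_npc = 0.07, median_charge = NULL, nup_charges = NULL,
                      lambda_nm = 1, epsilon = 80, temperature_k = 298.15) {
  if (radius_nm <= 0 || height_nm <= 0) abort("pore radius and height must be > 0")
  if (lambda_nm <= 0) abort("screening length must be > 0")
  if (temperature_k <= 0) abort("temperature must be > 0")
  if (epsilon < 1) abort("dielectric constant must be >= 1")
  if (species < 1 || copies < 1) abort("species and copies must be >= 1")
  structure(
    list(
      radius_nm = radius_nm, height_nm = height_nm,
      species = as.integer(species), copies = as.integer(copies),
      q_npc = q_npc, median_charge = median_charge, nup_charges = nup_charges,
      lambda_nm = lambda_nm, epsilon = epsilon, temperature_k = temperature_k
    ),
    class = "npc_model"
  )
}

#' @export
print.npc_model <- function(x, ...) {
  cat(sprintf(
    paste0("<npc_model> cylinder %g x %g nm, %d species x %d copies, ",
           "lambda %g nm, epsilon %g, T %g K\n  Q_NPC = %.4g e, ",
           "coefficient %.4g kBT per unit charge\n"),
    x$radius_nm, x$height_nm, x$species, x$copies,
    x$lambda_nm, x$epsilon, x$temperature_k,
    local_npc_charge(x), translocation_enthalpy(1, x)
  ))
  invisible(x)
}

#' Read NPC model parameters from a YAML or JSON config
#'
#' Recognized keys match the arguments of [npc_model()].
#'
#' @param path Path to the config file.
#' @return An `npc_model`.
#' @export
read_npc_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("NPC config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  known <- names(formals(npc_model))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown NPC config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(npc_model, cfg)
}

#' Pore volume of the NPC cylinder
#'
#' @param model An [npc_model()].
#' @return Volume in nm^3 (`pi * radius^2 * height`).
#' @export
#' @examples
#' pore_volume(npc_model())  # ~ 41,964 nm^3
pore_volume <- function(model) {
  stopifnot(inherits(model, "npc_model"))
  pi * model$radius_nm^2 * model$height_nm
}

#' Local nucleoporin charge within a screening-length hemisphere
#'
#' The expected FG-nucleoporin charge inside a hemisphere of radius
#' `lambda` at the particle surface. When `q_npc` is set on the model it
#' is returned directly; otherwise the uniform-density expectation
#' `(species * copies) * median charge * ((2/3) pi lambda^3 / pore volume)`
#' is used.
#'
#' @param model An [npc_model()].
#' @return Q_NPC in elementary charges.
#' @export
#' @examples
#' local_npc_charge(npc_model(q_npc = NULL, median_charge = 10))  # ~0.0519 e
local_npc_charge <- function(model) {
  stopifnot(inherits(model, "npc_model"))
  if (!is.null(model$q_npc)) return(model$q_npc)
  med <- model$median_charge
  if (is.null(med) && !is.null(model$nup_charges)) med <- median(model$nup_charges)
  if (is.null(med)) {
    abort("model supplies neither q_npc, median_charge nor nup_charges")
  }
  hemisphere <- (2 / 3) * pi * model$lambda_nm^3
  (model$species * model$copies) * med * hemisphere / pore_volume(model)
}

#' Screened-Coulomb pair interaction energy
#'
#' Energy of two effective charges separated by one screening length in a
#' dielectric medium, in thermal units:
#' `E = Q1 Q2 e^2 / (4 pi eps0 epsilon lambda) / (kB T)`.
#'
#' @param q1,q2 Charges in elementary-charge units (vectorized).
#' @param lambda_nm Separation / screening length (nm).
#' @param epsilon Relative dielectric constant.
#' @param temperature_k Temperature in K.
#' @return Energy in units of kB*T.
#' @export
#' @examples
#' pair_energy(1, 1)  # ~0.700 kBT for unit charges at 1 nm in water
pair_energy <- function(q1, q2, lambda_nm = 1, epsilon = 80,
                        temperature_k = 298.15) {
  if (any(lambda_nm <= 0)) abort("screening length must be > 0")
  if (any(temperature_k <= 0)) abort("temperature must be > 0")
  if (any(epsilon < 1)) abort("dielectric constant must be >= 1")
  joules <- q1 * q2 * E_CHARGE^2 /
    (4 * pi * EPSILON0 * epsilon * lambda_nm * 1e-9)
  joules / (K_BOLTZ * temperature_k)
}

#' Electrostatic translocation enthalpy
#'
#' The enthalpy change for a particle of net charge `q_ntr` entering the
#' NPC: the screened-Coulomb interaction between the particle charge and
#' the local barrier charge Q_NPC. Linear in `q_ntr`; with the default
#' model each added negative charge lowers the energy by ~0.05 kBT, and a
#' typical transport receptor (Q ~ -50 e) gains ~-2.5 kBT.
#'
#' @param q_ntr Particle net charge in e (vectorized).
#' @param model An [npc_model()].
#' @return Enthalpy in kBT units (negative = energy gain).
#' @export
#' @examples
#' translocation_enthalpy(-50, npc_model())  # ~ -2.45 kBT
translocation_enthalpy <- function(q_ntr, model = npc_model()) {
  pair_energy(q_ntr, local_npc_charge(model),
              lambda_nm = model$lambda_nm, epsilon = model$epsilon,
              temperature_k = model$temperature_k)
}

#' Free-energy barrier from enthalpy and entropy
#'
#' `dG = dH - TdS`. The entropic cost of confinement is user-supplied;
#' this package models only the electrostatic enthalpy.
#'
#' @param delta_h Enthalpy in kBT.
#' @param t_delta_s Entropic term T*dS in kBT.
#' @return dG in kBT.
#' @export
barrier <- function(delta_h, t_delta_s) {
  if (any(!is.finite(delta_h)) || any(!is.finite(t_delta_s))) {
    abort("delta_h and t_delta_s must be finite")
  }
  delta_h - t_delta_s
}

#' Enthalpy shift from phosphorylation
#'
#' Each phosphorylated site adds `charge_per_site` (default -1 e) to the
#' particle charge; by linearity the barrier shifts by the corresponding
#' translocation enthalpy, ~-0.05 kBT per site under default parameters.
#'
#' @param n_sites Number of phosphorylated sites (>= 0, vectorized).
#' @param model An [npc_model()].
#' @param charge_per_site Charge added per site in e (default -1).
#' @return Enthalpy shift in kBT.
#' @export
phosphorylation_shift <- function(n_sites, model = npc_model(),
                                  charge_per_site = -1) {
  if (any(n_sites < 0)) abort("n_sites must be >= 0")
  translocation_enthalpy(n_sites * charge_per_site, model)
}

#' Electrostatic energy predictions for proteins and complexes
#'
#' Computes each subject's net charge at `pH` (for complexes, the
#' copy-weighted sum over member chains) and feeds it through the
#' screened-Coulomb model. Binding a positively charged cargo to
#' negatively charged receptors can flip the sign of the predicted
#' enthalpy — the mechanism by which receptor binding converts a barrier
#' into an energy gain.
#'
#' @param proteins Protein table (`id`, `sequence`, optional `label`).
#' @param model An [npc_model()].
#' @param manifest Optional complex manifest; complexes are predicted as
#'   additional rows.
#' @param ionization An [ionization_model()].
#' @param pH pH for the net charge (default 7.2).
#' @param t_delta_s Optional entropic term (kBT); when supplied, a
#'   `delta_g` column is added.
#' @return An `energy_prediction` tibble: `id`, `label`, `q_ntr` (e),
#'   `delta_h` (kBT), and optionally `t_delta_s`, `delta_g`.
#' @export
predict_particles <- function(proteins, model = npc_model(), manifest = NULL,
                              ionization = ionization_model(), pH = 7.2,
                              t_delta_s = NULL) {
  proteins <- check_proteins(proteins)
  out <- tibble::tibble(
    id = proteins$id,
    label = proteins$label,
    q_ntr = net_charge(proteins$sequence, pH = pH, ionization = ionization)
  )
  if (!is.null(manifest)) {
    manifest <- validate_manifest(manifest, proteins)
    charges <- setNames(out$q_ntr, out$id)
    cplx <- manifest |>
      dplyr::group_by(.data$complex) |>
      dplyr::summarise(q_ntr = sum(charges[.data$member] * .data$copies)) |>
      dplyr::transmute(id = .data$complex, label = "complex", q_ntr = .data$q_ntr)
    out <- dplyr::bind_rows(out, cplx)
  }
  out <- dplyr::mutate(out, delta_h = translocation_enthalpy(.data$q_ntr, model))
  if (!is.null(t_delta_s)) {
    out <- dplyr::mutate(out,
      t_delta_s = t_delta_s,
      delta_g = barrier(.data$delta_h, t_delta_s)
    )
  }
  structure(out, class = c("energy_prediction", class(out)), model = model)
}

#' @method autoplot energy_prediction
#' @export
autoplot.energy_prediction <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$q_ntr, y = .data$delta_h, color = .data$label
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = expression(Q[NTR] ~ "(e)"),
      y = expression(Delta * H ~ "(" * k[B] * T * ")"),
      color = NULL
    ) +
    ggplot2::theme_minimal(base_size = 10)
}

#' Tidy an NPC model's parameters
#'
#' @param x An [npc_model()].
#' @param ... Unused.
#' @return One row per parameter: `term`, `value`, `unit`.
#' @method tidy npc_model
#' @export
tidy.npc_model <- function(x, ...) {
  tibble::tibble(
    term = c("radius", "height", "species", "copies", "lambda",
             "epsilon", "temperature", "q_npc"),
    value = c(x$radius_nm, x$height_nm, x$species, x$copies, x$lambda_nm,
              x$epsilon, x$temperature_k, local_npc_charge(x)),
    unit = c("nm", "nm", "count", "count", "nm", "", "K", "e")
  )
}

#' One-row summary of an NPC model
#'
#' @param x An [npc_model()].
#' @param ... Unused.
#' @return A tibble with `pore_volume_nm3`, `q_npc_e` and
#'   `kbt_per_unit_charge` (the linear coefficient of the enthalpy in the
#'   particle charge).
#' @method glance npc_model
#' @export
glance.npc_model <- function(x, ...) {
  tibble::tibble(
    pore_volume_nm3 = pore_volume(x),
    q_npc_e = local_npc_charge(x),
    kbt_per_unit_charge = translocation_enthalpy(1, x)
  )
}
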