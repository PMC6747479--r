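# Physical constants (SI). CODATA 2018; kB and hbar are exact in the 2019 SI.
.const <- list(
  kb   = 1.380649e-23,      # Boltzmann constant, J K^-1
  hbar = 1.054571817e-34,   # reduced Planck constant, J s
  mu0  = 1.25663706212e-6   # vacuum permeability, N A^-2
)

# Nuclei registry. gamma in rad s^-1 T^-1 (signed, CODATA).
# frequency_ratio is the IUPAC referencing ratio Xi relative to 1H; for 13C
# and 15N the DSS-based values conventionally used for indirect referencing
# are pinned; they agree with |gamma/gamma_1H| to within 0.1%.
.nuclei_tbl <- tibble::tibble(
  name = c("1H", "2H", "13C", "15N", "31P"),
  gamma = c(2.6752218744e8, 4.10662791e7, 6.728284e7, -2.7126180e7, 1.08394e8),
  frequency_ratio = c(1, 0.153506088, 0.251449530, 0.101329118, 0.404808636)
)

#' Registry of NMR-active nuclei
#'
#' The nuclei used throughout the package: `1H`, `2H`, `13C`, `15N` and
#' `31P`, with signed gyromagnetic ratios (rad s^-1 T^-1) and the Larmor
#' frequency ratio relative to `1H` used for indirect referencing.
#'
#' @return A tibble with columns `name`, `gamma`, `frequency_ratio`.
#' @export
#' @examples
#' nuclei()
nuclei <- function() .nuclei_tbl

#' Look up a single nucleus
#'
#' @param name Isotope label, e.g. `"15N"`.
#' @return A one-row tibble with columns `name`, `gamma`, `frequency_ratio`.
#' @export
#' @examples
#' nucleus("31P")
nucleus <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  hit <- .nuclei_tbl[.nuclei_tbl$name == name, ]
  if (nrow(hit) == 0) {
    abort(paste0("unknown nucleus '", name, "'; registered: ",
                 paste(.nuclei_tbl$name, collapse = ", ")),
          class = "micellr_registry_error")
  }
  hit
}

#' Convert between gyromagnetic ratio and Larmor frequency ratio
#'
#' Pure unit conversions against the `1H` gyromagnetic ratio; exact inverses
#' of one another.
#'
#' @param gamma Gyromagnetic ratio (rad s^-1 T^-1, signed).
#' @param ratio Larmor frequency ratio relative to `1H` (positive).
#' @return Numeric.
#' @export
frequency_ratio_from_gamma <- function(gamma) {
  abs(gamma) / .nuclei_tbl$gamma[.nuclei_tbl$name == "1H"]
}

#' @rdname frequency_ratio_from_gamma
#' @export
gamma_from_frequency_ratio <- function(ratio) {
  ratio * .nuclei_tbl$gamma[.nuclei_tbl$name == "1H"]
}

#' Specify a static magnetic field
#'
#' Either the flux density `b0` (tesla) or the `1H` resonance frequency
#' (Hz) may be given; the other is derived via the `1H` gyromagnetic ratio.
#' If both are supplied they must agree to 0.1%.
#'
#' @param b0 Magnetic flux density in tesla.
#' @param proton_frequency `1H` resonance frequency in Hz.
#' @return An object of class `field_spec`: list with `b0` and
#'   `proton_frequency`.
#' @export
#' @examples
#' field_spec(proton_frequency = 599.98e6) # the 14.1 T spectrometer
field_spec <- function(b0 = NULL, proton_frequency = NULL) {
  gamma_h <- .nuclei_tbl$gamma[.nuclei_tbl$name == "1H"]
  if (is.null(b0) && is.null(proton_frequency)) {
    abort("supply b0 and/or proton_frequency", class = "micellr_validation_error")
  }
  if (is.null(b0)) b0 <- 2 * pi * proton_frequency / gamma_h
  if (is.null(proton_frequency)) proton_frequency <- gamma_h * b0 / (2 * pi)
  stopifnot(b0 > 0, proton_frequency > 0)
  implied <- gamma_h * b0 / (2 * pi)
  if (abs(implied - proton_frequency) / proton_frequency > 1e-3) {
    abort(sprintf(
      "b0 (%.4g T implies %.6g MHz) and proton_frequency (%.6g MHz) disagree by more than 0.1%%",
      b0, implied / 1e6, proton_frequency / 1e6), class = "micellr_validation_error")
  }
  structure(list(b0 = b0, proton_frequency = proton_frequency),
            class = "field_spec")
}

#' Larmor frequency of a nucleus at a given field
#'
#' Computed as the nucleus' frequency ratio times the field's `1H`
#' frequency, so that indirectly referenced nuclei reproduce the
#' conventional referencing ratios exactly; this agrees with
#' `|gamma| * b0 / (2 * pi)` to within 0.1%.
#'
#' @param nuc Nucleus name or a row from [nuclei()].
#' @param field A [field_spec()].
#' @return Frequency in Hz.
#' @export
#' @examples
#' larmor_frequency("15N", field_spec(proton_frequency = 599.98e6))
larmor_frequency <- function(nuc, field) {
  if (is.character(nuc)) nuc <- nucleus(nuc)
  stopifnot(inherits(field, "field_spec"))
  nuc$frequency_ratio * field$proton_frequency
}

# Dynamic viscosity of pure water (mPa s) at 5 K steps, 273.15-373.15 K.
# Standard reference values; interpolation is linear in log(eta).
.water_visc <- tibble::tibble(
  temperature = 273.15 + seq(0, 100, by = 5),
  eta_mpas = c(1.7911, 1.5182, 1.3060, 1.1375, 1.0016, 0.8900, 0.7972,
               0.7190, 0.6527, 0.5958, 0.5465, 0.5042, 0.4666, 0.4334,
               0.4039, 0.3774, 0.3544, 0.3340, 0.3150, 0.2975, 0.2822)
)

#' Dynamic viscosity of an H2O/D2O mixture
#'
#' Pure-water viscosity from a reference anchor table (5 K steps,
#' 273.15-373.15 K) interpolated linearly in `log(eta)`, with a
#' multiplicative heavy-water correction linear in the D2O volume
#' fraction (factor 1.23 at fraction 1, the D2O/H2O viscosity ratio
#' near room temperature).
#'
#' @param temperature Absolute temperature in K.
#' @param d2o_fraction Volume fraction of D2O, in `[0, 1]`.
#' @return Dynamic viscosity in Pa s.
#' @export
#' @examples
#' solvent_viscosity(303.15)        # ~0.797e-3 Pa s
#' solvent_viscosity(303, 0.1)      # the 90/10 H2O/D2O NMR buffer
solvent_viscosity <- function(temperature, d2o_fraction = 0) {
  stopifnot(all(d2o_fraction >= 0), all(d2o_fraction <= 1))
  rng <- range(.water_visc$temperature)
  if (any(temperature < rng[1] | temperature > rng[2])) {
    abort(sprintf("temperature outside tabulated range [%.2f, %.2f] K",
                  rng[1], rng[2]), class = "micellr_range_error")
  }
  log_eta <- stats::approx(.water_visc$temperature, log(.water_visc$eta_mpas),
                           xout = temperature)$y
  exp(log_eta) * 1e-3 * (1 + 0.23 * d2o_fraction)
}

#' Specify the solvent
#'
#' @param temperature Absolute temperature in K.
#' @param d2o_fraction Volume fraction of D2O, in `[0, 1]`.
#' @param viscosity Dynamic viscosity in Pa s; derived from the reference
#'   table via [solvent_viscosity()] when `NULL`.
#' @return An object of class `solvent_spec`.
#' @export
solvent_spec <- function(temperature, d2o_fraction = 0, viscosity = NULL) {
  stopifnot(temperature > 0, d2o_fraction >= 0, d2o_fraction <= 1)
  if (is.null(viscosity)) viscosity <- solvent_viscosity(temperature, d2o_fraction)
  stopifnot(viscosity > 0)
  structure(list(temperature = temperature, d2o_fraction = d2o_fraction,
                 viscosity = viscosity), class = "solvent_spec")
}

#' Micelle-to-peptide stoichiometry
#'
#' Number of micelles per peptide molecule from the detergent
#' concentration, the critical micelle concentration (CMC), the mean
#' aggregation number and the peptide concentration. By default the total
#' detergent concentration is used; with
#' `correct_free_monomer = TRUE` the CMC-worth of free monomer is
#' subtracted first.
#'
#' @param c_detergent Total detergent concentration (mM).
#' @param cmc Critical micelle concentration (mM).
#' @param n_agg Mean aggregation number (molecules per micelle).
#' @param c_peptide Peptide concentration (mM).
#' @param correct_free_monomer Subtract the free-monomer (CMC) pool?
#' @return Micelle:peptide ratio (dimensionless).
#' @export
#' @examples
#' # 110 mM SDS (cmc 8.3 mM, aggregation number 55) with 1 mM peptide
#' micelles_per_peptide(110, 8.3, 55, 1)        # = 2: two micelles per peptide
#' micelles_per_peptide(110, 8.3, 55, 1, TRUE)  # ~1.85 with monomer correction
micelles_per_peptide <- function(c_detergent, cmc, n_agg, c_peptide,
                                 correct_free_monomer = FALSE) {
  stopifnot(n_agg >= 1, c_peptide > 0, cmc >= 0, c_detergent > 0)
  if (correct_free_monomer) {
    if (c_detergent <= cmc) {
      abort("detergent concentration at or below the CMC: no micelles form",
            class = "micellr_infeasible_micelle_error")
    }
    c_mic <- c_detergent - cmc
  } else {
    c_mic <- c_detergent
  }
  c_mic / n_agg / c_peptide
}

#' Physical constants used by the package
#'
#' @return Named list with `kb` (J K^-1), `hbar` (J s), `mu0` (N A^-2).
#' @export
physical_constants <- function() .const
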