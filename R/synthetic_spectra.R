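#' Stage presets for the assembly conditions
#'
#' Named parameter sets keyed to assembly temperature and duration. Each
#' preset records the secondary-structure composition (area percent
#' beta/coil/turn) where reported, the characteristic apparent rod or
#' oligomer height (nm), the mean rod length (nm) where reported for the
#' 300-min states, and whether the morphology at that stage is oligomeric
#' blobs or short rods. Compositions at 348 K and the later 299 K stages
#' were not printed as numbers and are `NA`; the 26/7 coil/turn split at
#' 299K-15min is a nominal split carried only so the generator can emit a
#' full band (its beta value is the meaningful one).
#'
#' @param name preset name like `"279K-15min"`; `NULL` returns the full
#'   table.
#' @return One preset as a list (with fields `name`, `temperature_K`,
#'   `duration_min`, `f_beta`, `f_coil`, `f_turn`, `height_nm`,
#'   `mean_length_nm`, `morphology`) or the whole data.frame.
#' @export
stage_preset <- function(name = NULL) {
  tab <- stage_preset_table()
  if (is.null(name)) return(tab)
  i <- match(name, tab$name)
  if (is.na(i))
    snf_abort(sprintf("unknown preset '%s'; see stage_preset()", name),
              "unknown_preset")
  as.list(tab[i, ])
}

stage_preset_table <- function() {
  tab <- data.frame(
    name = c("279K-15min", "279K-60min", "279K-300min",
             "299K-15min", "299K-60min", "299K-300min",
             "348K-15min", "348K-60min", "348K-300min"),
    temperature_K = rep(c(279, 299, 348), each = 3),
    duration_min = rep(c(15, 60, 300), 3),
    f_beta = c(79, 57, 49, 67, NA, NA, NA, NA, NA),
    f_coil = c(14, 40, 41, 26, NA, NA, NA, NA, NA),
    f_turn = c(7, 3, 10, 7, NA, NA, NA, NA, NA),
    height_nm = c(0.8, 3.5, 4.1, 1.2, 4.8, 4.9, 3.3, 4.8, 6.2),
    mean_length_nm = c(NA, NA, 17, NA, NA, 24, NA, NA, 95),
    morphology = c("oligomer", "rod", "rod", "oligomer", "rod", "rod",
                   "rod", "rod", "rod"),
    stringsAsFactors = FALSE)
  tab
}

#' Gate-tunable graphene plasmon model
#'
#' The plasmon resonance follows a quarter-power gate law,
#' omega_p = kappa * |V_G - V_CNP|^(1/4), reflecting the graphene plasmon
#' frequency scaling with carrier density^(1/4) and carrier density with
#' gate overdrive. `kappa` defaults to 1600 / 100^(1/4) cm^-1 V^(-1/4) so
#' a 100 V overdrive parks the resonance at 1600 cm^-1, over the amide
#' bands.
#'
#' @param v_g gate voltage (V).
#' @param v_cnp charge-neutral-point voltage (V).
#' @param kappa gate-law prefactor (cm^-1 V^(-1/4)).
#' @param gamma_p plasmon linewidth (cm^-1).
#' @param amplitude peak extinction of the uncoupled plasmon.
#' @param doping_dv accumulated doping shift (V, <= 0), applied as a
#'   reduction of the effective gate overdrive magnitude.
#' @return `snf_plasmon_model` with derived `omega_p`.
#' @export
plasmon_model <- function(v_g = 100, v_cnp = 0,
                          kappa = 1600 / 100^0.25,
                          gamma_p = 150, amplitude = 0.3,
                          doping_dv = 0) {
  if (gamma_p <= 0) snf_abort("gamma_p must be positive", "domain")
  if (doping_dv > 0) snf_abort("doping_dv must be <= 0", "domain")
  dv_eff <- max(abs(v_g - v_cnp) + doping_dv, 0)
  structure(list(v_g = v_g, v_cnp = v_cnp, kappa = kappa,
                 gamma_p = gamma_p, amplitude = amplitude,
                 doping_dv = doping_dv,
                 omega_p = kappa * dv_eff^0.25),
            class = "snf_plasmon_model")
}

#' Red-shift the plasmon by adsorbate doping
#'
#' Adsorption of the negatively charged protein dopes the graphene and
#' red-shifts the plasmon at fixed measurement gate voltage. The shift is
#' modelled as a reduction `delta_v` (<= 0) of the effective gate
#' overdrive magnitude, so the quarter-power law then yields a lower
#' resonance on either side of the charge-neutral point.
#'
#' @param plasmon a [plasmon_model()].
#' @param delta_v doping-equivalent gate shift in V, `<= 0`.
#' @return The shifted `snf_plasmon_model`.
#' @export
apply_doping_shift <- function(plasmon, delta_v) {
  stopifnot(inherits(plasmon, "snf_plasmon_model"))
  if (delta_v > 0) snf_abort("delta_v must be <= 0 (doping red-shift)", "domain")
  plasmon_model(v_g = plasmon$v_g, v_cnp = plasmon$v_cnp,
                kappa = plasmon$kappa, gamma_p = plasmon$gamma_p,
                amplitude = plasmon$amplitude,
                doping_dv = plasmon$doping_dv + delta_v)
}

#' Vibrational mode coupled to the plasmon
#'
#' @param omega_v mode frequency (cm^-1), e.g. 1626 (amide I) or 1538
#'   (amide II).
#' @param gamma_v mode linewidth (cm^-1).
#' @param g coupling strength (cm^-1); `g = 0` decouples the mode.
#' @return `snf_vib_mode`.
#' @export
vibrational_mode <- function(omega_v, gamma_v = 12, g = 25) {
  if (gamma_v <= 0) snf_abort("gamma_v must be positive", "domain")
  if (g < 0) snf_abort("coupling g must be >= 0", "domain")
  structure(list(omega_v = omega_v, gamma_v = gamma_v, g = g),
            class = "snf_vib_mode")
}

#' Simulate a plasmon-enhanced extinction spectrum
#'
#' Classical coupled-oscillator forward model of the Fano-type destructive
#' interference between the bright, field-driven graphene plasmon and
#' dark molecular vibrations. The bright-mode response is
#' `chi(omega) = 1 / (D_p(omega) - sum_k (g_k * omega_k)^2 / D_k(omega))`
#' with `D_m(omega) = omega_m^2 - omega^2 - i * gamma_m * omega_m`; the
#' extinction is the imaginary part, normalized so the uncoupled plasmon
#' peak equals the model amplitude. Coupled modes carve dips into the
#' plasmon peak at their own frequencies, deepening with `g`.
#'
#' @param plasmon a [plasmon_model()].
#' @param modes list of [vibrational_mode()] objects (may be empty).
#' @param grid wavenumber grid (cm^-1); must cover every mode +/- 5
#'   linewidths. A warning is raised when the grid step exceeds half the
#'   narrowest mode linewidth.
#' @return `snf_spectrum` of kind `extinction`.
#' @export
simulate_extinction <- function(plasmon, modes = list(),
                                grid = seq(1000, 2400, by = 2)) {
  stopifnot(inherits(plasmon, "snf_plasmon_model"))
  for (m in modes) {
    stopifnot(inherits(m, "snf_vib_mode"))
    if (min(grid) > m$omega_v - 5 * m$gamma_v ||
        max(grid) < m$omega_v + 5 * m$gamma_v)
      snf_abort("grid does not cover a mode +/- 5 linewidths", "range")
    if (stats::median(diff(grid)) > m$gamma_v / 2)
      snf_warn("grid step exceeds half a mode linewidth", "resolution")
  }
  Dp <- plasmon$omega_p^2 - grid^2 - 1i * plasmon$gamma_p * plasmon$omega_p
  sigma <- 0
  for (m in modes) {
    Dv <- m$omega_v^2 - grid^2 - 1i * m$gamma_v * m$omega_v
    sigma <- sigma + (m$g * m$omega_v)^2 / Dv
  }
  chi <- Im(1 / (Dp - sigma))
  chi0_max <- Im(1 / (-1i * plasmon$gamma_p * plasmon$omega_p))
  spectrum(grid, plasmon$amplitude * chi / chi0_max, "extinction")
}

#' Synthetic amide I Delta-Extinction band for a stage preset
#'
#' Sum of three Gaussians at 1626 / 1650 / 1674 cm^-1 (sigma 8 / 12 / 10
#' cm^-1) whose heights are solved so the analytic area fractions equal
#' the preset composition, scaled so the band maximum equals `amplitude`,
#' plus seeded white noise of standard deviation `noise_frac` times the
#' band maximum.
#'
#' @param preset preset name (see [stage_preset()]) or a preset list; its
#'   composition must be non-`NA`.
#' @param noise_frac noise SD as a fraction of the band maximum (>= 0).
#' @param seed integer RNG seed.
#' @param grid wavenumber grid.
#' @param amplitude band maximum in Delta-Extinction units.
#' @return `snf_spectrum` of kind `delta_extinction`.
#' @export
make_amide_band <- function(preset, noise_frac = 0.01, seed = 1,
                            grid = seq(1560, 1740, by = 1),
                            amplitude = 0.01) {
  if (is.character(preset)) preset <- stage_preset(preset)
  if (noise_frac < 0) snf_abort("noise_frac must be >= 0", "domain")
  comp <- c(preset$f_beta, preset$f_coil, preset$f_turn)
  if (any(is.na(comp)))
    snf_abort(sprintf("preset '%s' has no printed composition", preset$name),
              "unknown_preset")
  centers <- c(1626, 1650, 1674)
  sigmas <- c(8, 12, 10)
  h <- comp / sigmas           # area_k ~ h_k * sigma_k proportional to f_k
  clean <- h[1] * exp(-(grid - centers[1])^2 / (2 * sigmas[1]^2)) +
    h[2] * exp(-(grid - centers[2])^2 / (2 * sigmas[2]^2)) +
    h[3] * exp(-(grid - centers[3])^2 / (2 * sigmas[3]^2))
  clean <- clean * amplitude / max(clean)
  noisy <- with_seed(seed, clean + stats::rnorm(length(grid),
                                                sd = noise_frac * max(clean)))
  spectrum(grid, noisy, "delta_extinction")
}
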