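#' Secondary-structure class windows for the amide I band
#'
#' Center windows for the three resolved Gaussian components: beta-sheet
#' 1616-1637 cm^-1, random coil 1638-1662 cm^-1, turn 1663-1685 cm^-1.
#' The weak 1685-1700 cm^-1 intramolecular beta-sheet contribution is not
#' modelled.
#' @return named list of `c(lo, hi)` windows.
#' @export
structure_windows <- function() {
  list(beta = c(1616, 1637), coil = c(1638, 1662), turn = c(1663, 1685))
}

#' Deconvolution configuration
#'
#' @param fwhm_bounds full-width-at-half-maximum bounds (cm^-1) shared by
#'   all three components; default 10-45 cm^-1.
#' @param start_centers starting centers; default class-window midpoints.
#' @param start_sigma starting Gaussian sigma in cm^-1.
#' @param n_starts number of deterministic jittered multistarts.
#' @param seed seed controlling the multistart jitter (part of the fit
#'   fingerprint, so a given config is fully reproducible).
#' @param start_jitter relative jitter applied to starting centers/widths
#'   across multistarts.
#' @return list of class `snf_deconv_config`.
#' @export
deconv_config <- function(fwhm_bounds = c(10, 45),
                          start_centers = NULL,
                          start_sigma = 12,
                          n_starts = 8,
                          seed = 1,
                          start_jitter = 0.15) {
  if (fwhm_bounds[1] <= 0 || fwhm_bounds[1] >= fwhm_bounds[2])
    snf_abort("invalid FWHM bounds", "domain")
  win <- structure_windows()
  if (is.null(start_centers)) start_centers <- vapply(win, mean, 0)
  structure(list(fwhm_bounds = fwhm_bounds, start_centers = start_centers,
                 start_sigma = start_sigma, n_starts = n_starts,
                 seed = seed, start_jitter = start_jitter),
            class = "snf_deconv_config")
}

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

gaussian3 <- function(wn, par) {
  # par = (mu1..3, sigma1..3, h1..3)
  par[7] * exp(-(wn - par[1])^2 / (2 * par[4]^2)) +
    par[8] * exp(-(wn - par[2])^2 / (2 * par[5]^2)) +
    par[9] * exp(-(wn - par[3])^2 / (2 * par[6]^2))
}

#' Constrained three-Gaussian deconvolution of the amide I band
#'
#' Fits a sum of three Gaussians to a Delta-Extinction band by bounded
#' Levenberg-Marquardt least squares. Centers are confined to the
#' secondary-structure class windows ([structure_windows()]), heights are
#' non-negative, and widths are confined to the configured FWHM bounds.
#' Eight deterministically jittered starting points are tried and the best
#' residual wins; residual ties below 1e-12 are broken by the lower
#' beta-sheet center. The result is a deterministic function of the band
#' and the config fingerprint.
#'
#' @param band `snf_spectrum` of kind `delta_extinction` covering
#'   1600-1700 cm^-1 with at least 25 points and a positive maximum.
#' @param config a [deconv_config()].
#' @return `snf_deconv_result`: `components` (data.frame with class, center,
#'   sigma, height, area), `rms` residual, `fingerprint`, and
#'   `boundary_hit` flag set when a fitted parameter sits on a bound.
#' @export
deconvolve_amide_I <- function(band, config = deconv_config()) {
  stopifnot(inherits(band, "snf_spectrum"))
  wn <- band$wavenumbers
  y <- band$values
  if (min(wn) > 1600 || max(wn) < 1700)
    snf_abort("band must cover 1600-1700 cm-1", "range")
  if (length(wn) < 25)
    snf_abort("band has fewer than 25 points", "degenerate_input")
  if (max(y) <= 0)
    snf_abort("band maximum must be positive (all-zero band?)",
              "degenerate_input")

  win <- structure_windows()
  slo <- config$fwhm_bounds[1] * FWHM_TO_SIGMA
  shi <- config$fwhm_bounds[2] * FWHM_TO_SIGMA
  lower <- c(win$beta[1], win$coil[1], win$turn[1], rep(slo, 3), rep(0, 3))
  upper <- c(win$beta[2], win$coil[2], win$turn[2], rep(shi, 3),
             rep(10 * max(y), 3))
  sig0 <- min(max(config$start_sigma, slo), shi)
  base_start <- c(config$start_centers, rep(sig0, 3), rep(max(y) / 2, 3))

  starts <- with_seed(config$seed, {
    lapply(seq_len(config$n_starts), function(k) {
      if (k == 1) return(base_start)
      s <- base_start
      widths <- c(diff(win$beta), diff(win$coil), diff(win$turn))
      s[1:3] <- s[1:3] + stats::runif(3, -0.5, 0.5) * widths * config$start_jitter * 2
      s[4:6] <- s[4:6] * exp(stats::runif(3, -1, 1) * config$start_jitter)
      s[7:9] <- s[7:9] * exp(stats::runif(3, -1, 1) * config$start_jitter)
      pmin(pmax(s, lower + 1e-9), upper - 1e-9)
    })
  })

  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = s, lower = lower, upper = upper,
      fn = function(p) y - gaussian3(wn, p),
      control = minpack.lm::nls.lm.control(maxiter = 400)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    res <- sqrt(mean(fit$fvec^2))
    if (is.null(best) || res < best$res - 1e-12 ||
        (abs(res - best$res) <= 1e-12 && fit$par[1] < best$par[1])) {
      best <- list(par = fit$par, res = res)
    }
  }
  if (is.null(best))
    snf_abort("no multistart converged", "convergence")

  p <- best$par
  on_bound <- any(abs(p - lower) < 1e-6 * pmax(1, abs(lower))) ||
    any(abs(p[1:6] - upper[1:6]) < 1e-6 * pmax(1, abs(upper[1:6])))
  if (on_bound)
    snf_warn("a fitted parameter sits on a constraint boundary", "boundary_hit")

  comp <- data.frame(
    class = c("beta", "coil", "turn"),
    center = p[1:3], sigma = p[4:6], height = p[7:9],
    area = p[7:9] * p[4:6] * sqrt(2 * pi),
    stringsAsFactors = FALSE)
  fingerprint <- paste0(
    "fwhm=", paste(config$fwhm_bounds, collapse = "-"),
    ";starts=", config$n_starts, ";seed=", config$seed,
    ";jitter=", config$start_jitter, ";sigma0=", config$start_sigma)
  structure(list(components = comp, rms = best$res,
                 fingerprint = fingerprint, boundary_hit = on_bound),
            class = "snf_deconv_result")
}

#' @export
print.snf_deconv_result <- function(x, ...) {
  cat("<snf_deconv_result>\n")
  print(x$components, digits = 5)
  cat(sprintf("residual RMS: %.3g\n", x$rms))
  invisible(x)
}

#' Secondary-structure content from fitted components
#'
#' Area percentages of the three resolved peaks: each component's analytic
#' area is height * sigma * sqrt(2*pi) and the content is 100 * area /
#' total area.
#'
#' @param result a `snf_deconv_result` (or a list of them, pooled as
#'   ensemble runs with per-class mean and SEM).
#' @return `snf_structure_content`: data.frame with `class`, `percent`,
#'   `sem`, plus `n_runs`.
#' @export
content_from_components <- function(result) {
  results <- if (inherits(result, "snf_deconv_result")) list(result) else result
  stopifnot(all(vapply(results, inherits, TRUE, "snf_deconv_result")))
  per_run <- vapply(results, function(r) {
    a <- r$components$area
    tot <- sum(a)
    if (tot <= 0) snf_abort("total fitted area is zero", "degenerate_input")
    100 * a / tot
  }, numeric(3))
  per_run <- matrix(per_run, nrow = 3)
  out <- data.frame(
    class = c("beta", "coil", "turn"),
    percent = rowMeans(per_run),
    sem = apply(per_run, 1, sem),
    stringsAsFactors = FALSE)
  structure(list(content = out, n_runs = ncol(per_run), runs = per_run),
            class = "snf_structure_content")
}

#' @export
print.snf_structure_content <- function(x, ...) {
  cat(sprintf("<secondary-structure content, %d run(s)>\n", x$n_runs))
  print(x$content, digits = 4)
  invisible(x)
}

#' Default fit-perturbation plan for ensemble uncertainty
#'
#' Emulates the practice of refitting each measured spectrum under varied
#' fitting choices (FWHM bounds, starting points) so the spread of the
#' ensemble reflects fit-configuration sensitivity as well as measurement
#' noise.
#'
#' @param fwhm_variants list of FWHM bound pairs.
#' @param jitter_starts logical, jitter starting points per variant.
#' @return list of class `snf_perturbation_plan`.
#' @export
perturbation_plan <- function(fwhm_variants = list(c(10, 45), c(8, 50), c(12, 40)),
                              jitter_starts = TRUE) {
  structure(list(fwhm_variants = fwhm_variants, jitter_starts = jitter_starts),
            class = "snf_perturbation_plan")
}

#' Ensemble deconvolution over replicate spectra
#'
#' Runs [deconvolve_amide_I()] on every replicate under every variant of
#' the perturbation plan and pools all runs into per-class mean and SEM
#' (sd/sqrt(n) over runs). Variant seeds are enumerated deterministically
#' from `seed`, so the whole ensemble is reproducible bit-for-bit.
#'
#' @param replicates list of >= 2 Delta-Extinction band spectra.
#' @param plan a [perturbation_plan()], or `NULL` for a single unperturbed
#'   fit per replicate.
#' @param seed integer controlling multistart jitter enumeration.
#' @return `snf_structure_content` pooled over all runs.
#' @export
ensemble_fit <- function(replicates, plan = perturbation_plan(), seed = 1) {
  if (length(replicates) < 2)
    snf_abort("ensemble_fit needs at least 2 replicates", "degenerate_input")
  variants <- if (is.null(plan)) list(c(10, 45)) else plan$fwhm_variants
  jitter <- if (is.null(plan)) 0 else if (plan$jitter_starts) 0.15 else 0
  runs <- list()
  failures <- character()
  for (r in seq_along(replicates)) {
    for (v in seq_along(variants)) {
      cfg <- deconv_config(fwhm_bounds = variants[[v]],
                           seed = seed + 131L * r + 17L * v,
                           start_jitter = jitter)
      fit <- try(suppressWarnings(deconvolve_amide_I(replicates[[r]], cfg)),
                 silent = TRUE)
      if (inherits(fit, "try-error")) {
        failures <- c(failures, sprintf("replicate %d variant %d", r, v))
      } else {
        runs[[length(runs) + 1L]] <- fit
      }
    }
  }
  if (length(failures) > 0)
    snf_abort(paste("ensemble runs failed:", paste(failures, collapse = "; ")),
              "partial_result", failures = failures)
  content_from_components(runs)
}
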