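#' Baseline model configuration
#'
#' The baseline is the smooth plasmon envelope against which vibrational
#' dips are measured. Four functional forms are offered:
#'
#' * `"plasmon"` (default): a Lorentzian-plus-offset resonance profile --
#'   the physical shape of the graphene plasmon peak -- fitted with
#'   asymmetric weights (points falling below the current envelope, i.e.
#'   candidate dips, are iteratively downweighted to `p`), followed by a
#'   stiff Whittaker smoother on the weighted residual to absorb slow
#'   non-Lorentzian deviations of the envelope. This tracks the plasmon
#'   peak even when its maximum lies inside the vibrational window, which
#'   no fit anchored only outside 1500-1700 cm^-1 can do.
#' * `"whittaker"`: purely non-parametric Whittaker smoother
#'   (second-difference penalty, stiffness `lambda`) with the same
#'   asymmetric reweighting.
#' * `"spline"`: a smoothing spline fitted on the anchor regions only and
#'   evaluated across the full grid.
#' * `"poly"`: a polynomial (degree 3-5) fitted on the anchor regions.
#'
#' The anchor regions default to everything outside 1500-1700 cm^-1, which
#' excludes both amide I and amide II; anchor points keep full weight in
#' every form.
#'
#' @param form `"plasmon"`, `"whittaker"`, `"spline"` or `"poly"`.
#' @param anchors list of `c(lo, hi)` wavenumber intervals used at full
#'   weight; the complement of `exclude` by default.
#' @param exclude interval treated as the vibrational region.
#' @param lambda Whittaker stiffness, expressed for a 1 cm^-1 grid step and
#'   rescaled internally as `lambda * (1/h)^4` so the physical smoothing
#'   window is grid independent.
#' @param p asymmetric weight given to sub-envelope points.
#' @param iterations number of reweighting passes.
#' @param degree polynomial degree for `form = "poly"`.
#' @param spar smoothing parameter for `form = "spline"` (NULL = GCV).
#' @return list of class `snf_baseline_config`.
#' @export
baseline_config <- function(form = c("plasmon", "whittaker", "spline", "poly"),
                            anchors = NULL,
                            exclude = c(1500, 1700),
                            lambda = 1e6, p = 1e-3, iterations = 20,
                            degree = 4, spar = NULL) {
  form <- match.arg(form)
  if (degree < 3 || degree > 5)
    snf_abort("polynomial baseline degree must be 3-5", "domain")
  structure(list(form = form, anchors = anchors, exclude = exclude,
                 lambda = lambda, p = p, iterations = iterations,
                 degree = degree, spar = spar),
            class = "snf_baseline_config")
}

# second-difference penalty solve: (W + lam D'D) z = W y
whittaker_solve <- function(y, w, lam) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  A <- Matrix::Diagonal(n, x = w) + lam * Matrix::crossprod(D)
  as.numeric(Matrix::solve(A, w * y))
}

#' Fit the plasmon envelope baseline
#'
#' @param spec an extinction `snf_spectrum` covering at least the excluded
#'   vibrational region (and ideally 1400-1800 cm^-1).
#' @param config a [baseline_config()].
#' @return Object of class `snf_baseline`: the fitted envelope on the input
#'   grid plus the configuration used.
#' @export
fit_baseline <- function(spec, config = baseline_config()) {
  stopifnot(inherits(spec, "snf_spectrum"))
  wn <- spec$wavenumbers
  y <- spec$values
  if (min(wn) > config$exclude[1] || max(wn) < config$exclude[2])
    snf_abort("spectrum does not cover the excluded vibrational region", "range")
  anchors <- config$anchors
  if (is.null(anchors)) {
    anchors <- list(c(-Inf, config$exclude[1]), c(config$exclude[2], Inf))
  }
  in_anchor <- Reduce(`|`, lapply(anchors, function(iv) wn >= iv[1] & wn <= iv[2]))
  if (sum(in_anchor) < 10)
    snf_abort("fewer than 10 grid points in the anchor regions",
              "insufficient_anchor")
  in_excl <- wn > config$exclude[1] & wn < config$exclude[2]

  base <- switch(config$form,
    plasmon = {
      # asymmetric IRLS on a Lorentzian resonance profile; candidate dip
      # points (below the current envelope by more than eps) get weight p
      span <- max(y) - min(y)
      par0 <- c(A = max(span, 1e-12), w0 = wn[which.max(y)],
                g = diff(range(wn)) / 4, c0 = min(y))
      lorentz <- function(p, x) p[1] / (1 + ((x - p[2]) / p[3])^2) + p[4]
      w <- rep(1, length(y))
      fitp <- par0
      for (i in seq_len(config$iterations)) {
        fit <- minpack.lm::nls.lm(
          par = fitp,
          lower = c(0, min(wn) - 2000, 10, -Inf),
          upper = c(Inf, max(wn) + 2000, 1e4, Inf),
          fn = function(p) sqrt(w) * (y - lorentz(p, wn)),
          control = minpack.lm::nls.lm.control(maxiter = 200))
        fitp <- fit$par
        z <- lorentz(fitp, wn)
        r <- y - z
        eps <- max(3 * stats::mad(r[in_anchor], center = 0), 1e-4 * span)
        w <- ifelse(in_anchor | r >= -eps, 1, config$p)
      }
      z <- lorentz(fitp, wn)
      # stiff residual smoother absorbs slow non-Lorentzian deviation
      h <- stats::median(diff(wn))
      s <- whittaker_solve(y - z, w, config$lambda / h^4)
      z + s
    },
    whittaker = {
      h <- stats::median(diff(wn))
      lam <- config$lambda / h^4
      w <- rep(1, length(y))
      z <- whittaker_solve(y, w, lam)
      for (i in seq_len(config$iterations)) {
        w <- ifelse(in_anchor | y >= z, 1, config$p)
        z <- whittaker_solve(y, w, lam)
      }
      z
    },
    spline = {
      fit <- stats::smooth.spline(wn[in_anchor], y[in_anchor],
                                  spar = config$spar)
      stats::predict(fit, wn)$y
    },
    poly = {
      d <- data.frame(x = wn, y = y)
      fit <- stats::lm(y ~ poly(x, degree = config$degree, raw = TRUE),
                       data = d[in_anchor, ])
      as.numeric(stats::predict(fit, newdata = d))
    })

  structure(list(wavenumbers = wn, values = base, config = config),
            class = "snf_baseline")
}

#' @export
print.snf_baseline <- function(x, ...) {
  cat(sprintf("<snf_baseline: %s, %d points>\n", x$config$form,
              length(x$wavenumbers)))
  invisible(x)
}

#' Delta-Extinction: baseline minus spectrum
#'
#' The sign convention makes vibrational dips on the plasmon envelope come
#' out as positive peaks, which is the orientation the amide-I
#' deconvolution expects.
#'
#' @param spec extinction spectrum.
#' @param baseline a fitted [fit_baseline()] object on the same grid.
#' @return `snf_spectrum` of kind `delta_extinction`.
#' @export
delta_extinction <- function(spec, baseline) {
  stopifnot(inherits(spec, "snf_spectrum"), inherits(baseline, "snf_baseline"))
  if (length(spec$wavenumbers) != length(baseline$wavenumbers) ||
      any(abs(spec$wavenumbers - baseline$wavenumbers) > 1e-9))
    snf_abort("baseline was not evaluated on the spectrum grid", "grid_mismatch")
  spectrum(spec$wavenumbers, baseline$values - spec$values, "delta_extinction")
}
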