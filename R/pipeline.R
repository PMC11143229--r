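#' Pipeline run configuration
#'
#' A run configuration names the stage presets to process, the stages to
#' execute, and every seed explicitly (no wall-clock seeding), so a run
#' is reproducible end to end.
#'
#' @param presets character vector of preset names (see [stage_preset()]).
#' @param stages subset of `"spectra"` (replicate amide-I bands +
#'   ensemble deconvolution) and `"afm"` (synthetic image + morphometry).
#' @param seed master integer seed; stage seeds are derived from it
#'   deterministically.
#' @param n_replicates spectra replicates per condition (>= 2).
#' @param noise_frac amide-band noise fraction.
#' @param afm list of AFM options: `size`, `pixel_nm`, `band`
#'   (height band for the length distribution), `min_height`.
#' @param outdir optional output directory for JSON/CSV reports.
#' @return list of class `snf_run_config`.
#' @export
run_config <- function(presets, stages = c("spectra", "afm"), seed = 1,
                       n_replicates = 4, noise_frac = 0.01,
                       afm = list(size = 512, pixel_nm = 2, band = c(3, 4),
                                  min_height = 1), outdir = NULL) {
  cfg <- list(presets = presets, stages = stages, seed = seed,
              n_replicates = n_replicates, noise_frac = noise_frac,
              afm = afm, outdir = outdir)
  class(cfg) <- "snf_run_config"
  cfg
}

#' Read a YAML run configuration
#'
#' @param path YAML file with the fields of [run_config()].
#' @return `snf_run_config` (unvalidated; see [validate_run_config()]).
#' @export
read_run_config <- function(path) {
  y <- tryCatch(yaml::read_yaml(path), error = function(e)
    snf_abort(paste("cannot parse config:", conditionMessage(e)), "parse"))
  known <- c("presets", "stages", "seed", "n_replicates", "noise_frac",
             "afm", "outdir")
  extra <- setdiff(names(y), known)
  cfg <- do.call(run_config, y[intersect(names(y), known)])
  attr(cfg, "unknown_keys") <- extra
  cfg
}

#' Validate a run configuration
#'
#' Pure check: returns a data.frame of findings (possibly empty) and
#' never mutates or executes anything.
#'
#' @param config a `snf_run_config`.
#' @return data.frame with columns `code` and `message`; zero rows when
#'   the configuration is clean.
#' @export
validate_run_config <- function(config) {
  f <- list()
  add <- function(code, msg) f[[length(f) + 1L]] <<- data.frame(code = code,
                                                                message = msg)
  if (length(config$stages) == 0) add("empty_stages", "stage list is empty")
  bad <- setdiff(config$stages, c("spectra", "afm"))
  if (length(bad)) add("unknown_stage", paste("unknown stage:",
                                              paste(bad, collapse = ", ")))
  known <- stage_preset()$name
  miss <- setdiff(config$presets, known)
  if (length(config$presets) == 0) add("no_presets", "no presets given")
  if (length(miss)) add("unknown_preset", paste("unknown preset:",
                                                paste(miss, collapse = ", ")))
  if (is.null(config$seed) || !is.finite(config$seed))
    add("missing_seed", "seed must be an explicit finite integer")
  if (!is.null(config$n_replicates) && config$n_replicates < 2)
    add("bad_replicates", "n_replicates must be >= 2")
  if (!is.null(config$noise_frac) && config$noise_frac < 0)
    add("bad_noise", "noise_frac must be >= 0")
  band <- config$afm$band
  if (!is.null(band) && !(band[1] < band[2]))
    add("bad_band", "height band lo must be < hi")
  uk <- attr(config, "unknown_keys")
  if (!is.null(uk) && length(uk))
    add("unknown_key", paste("unknown config key:", paste(uk, collapse = ", ")))
  if (length(f) == 0)
    return(data.frame(code = character(0), message = character(0)))
  do.call(rbind, f)
}

#' Run the assembly-kinetics pipeline
#'
#' For every preset condition (sorted by temperature, then duration):
#' generate replicate amide-I bands, deconvolve them as an ensemble, and
#' measure rod morphology from a synthetic AFM image; assemble everything
#' into a kinetics report. Every stage seed is derived from the master
#' seed and recorded in the per-condition fingerprint.
#'
#' @param config a `snf_run_config`.
#' @return `snf_kinetics_report`: per-condition secondary-structure
#'   content and morphology stats plus a provenance block. Written as
#'   JSON + CSV into `config$outdir` when set.
#' @export
run_pipeline <- function(config) {
  findings <- validate_run_config(config)
  if (nrow(findings) > 0)
    snf_abort(paste("invalid configuration:",
                    paste(findings$message, collapse = "; ")),
              "validation", findings = findings)
  tab <- stage_preset()
  sel <- tab[match(config$presets, tab$name), ]
  sel <- sel[order(sel$temperature_K, sel$duration_min), ]
  conditions <- list()
  for (k in seq_len(nrow(sel))) {
    p <- as.list(sel[k, ])
    cond <- list(preset = p$name, temperature_K = p$temperature_K,
                 duration_min = p$duration_min)
    fp <- list(master_seed = config$seed)
    if ("spectra" %in% config$stages && !is.na(p$f_beta)) {
      rep_seeds <- config$seed * 1000L + k * 10L + seq_len(config$n_replicates)
      stage_try(p$name, "spectra", {
        reps <- lapply(rep_seeds, function(s)
          window_amide_I(make_amide_band(p, config$noise_frac, seed = s)))
        ct <- suppressWarnings(ensemble_fit(reps, seed = config$seed + k))
        cond$content <- ct$content
        cond$n_runs <- ct$n_runs
        fp$replicate_seeds <- rep_seeds
        fp$ensemble_seed <- config$seed + k
      })
    }
    if ("afm" %in% config$stages) {
      aseed <- config$seed * 1000L + k * 10L + 7L
      stage_try(p$name, "afm", {
        img <- make_afm_image(p, "height", seed = aseed,
                              size = config$afm$size %||% 512,
                              pixel_nm = config$afm$pixel_nm %||% 2)
        seg <- segment_rods(img, detect_ribbons(img),
                            min_height = if (p$morphology == "oligomer") 0.4
                                         else config$afm$min_height %||% 1)
        n <- nrow(img$map)
        thirds <- list(c(1, n %/% 3, 1, ncol(img$map)),
                       c(n %/% 3 + 1, 2 * (n %/% 3), 1, ncol(img$map)),
                       c(2 * (n %/% 3) + 1, n, 1, ncol(img$map)))
        cond$height <- suppressWarnings(measure_heights(seg, thirds))
        fp$afm_height_seed <- aseed
        if (!is.na(p$mean_length_nm)) {
          limg <- make_afm_image(p, "length", seed = aseed + 1L,
                                 size = max(config$afm$size %||% 512, 1024),
                                 pixel_nm = config$afm$pixel_nm %||% 2)
          lseg <- segment_rods(limg, detect_ribbons(limg),
                               min_height = config$afm$min_height %||% 1)
          cond$length <- length_distribution(lseg,
                                             config$afm$band %||% c(3, 4))
          fp$afm_length_seed <- aseed + 1L
        }
      })
    }
    cond$fingerprint <- fp
    conditions[[p$name]] <- cond
  }
  report <- structure(list(conditions = conditions,
                           config = unclass(config)),
                      class = "snf_kinetics_report")
  if (!is.null(config$outdir)) write_kinetics_report(report, config$outdir)
  report
}

stage_try <- function(preset, stage, expr) {
  env <- parent.frame()
  tryCatch(eval(substitute(expr), env), error = function(e) {
    snf_abort(sprintf("stage '%s' failed for preset '%s': %s",
                      stage, preset, conditionMessage(e)), "stage_failure")
  })
}

#' @export
print.snf_kinetics_report <- function(x, ...) {
  cat("<snf_kinetics_report>\n")
  for (cond in x$conditions) {
    cat(sprintf(" %s:", cond$preset))
    if (!is.null(cond$content))
      cat(sprintf(" beta %.1f%%", cond$content$percent[1]))
    if (!is.null(cond$height))
      cat(sprintf(" height %.2f nm", cond$height$mean_nm))
    if (!is.null(cond$length) && !cond$length$empty)
      cat(sprintf(" length %.1f nm", cond$length$mean_length_nm))
    cat("\n")
  }
  invisible(x)
}

#' Write a kinetics report as JSON plus CSV tables
#'
#' @param report a `snf_kinetics_report`.
#' @param outdir output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
write_kinetics_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  payload <- lapply(report$conditions, function(cond) {
    out <- list(preset = cond$preset,
                temperature_K = cond$temperature_K,
                duration_min = cond$duration_min,
                fingerprint = cond$fingerprint)
    if (!is.null(cond$content))
      out$secondary_structure <- stats::setNames(
        as.list(cond$content$percent), cond$content$class)
    if (!is.null(cond$height))
      out$height_nm <- list(mean = cond$height$mean_nm,
                            sem = cond$height$sem_nm)
    if (!is.null(cond$length))
      out$length_nm <- list(mean = cond$length$mean_length_nm,
                            n = length(cond$length$lengths_nm))
    out
  })
  jsonlite::write_json(payload, file.path(outdir, "kinetics_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  rows <- do.call(rbind, lapply(report$conditions, function(cond) {
    data.frame(
      preset = cond$preset,
      temperature_K = cond$temperature_K,
      duration_min = cond$duration_min,
      beta = if (!is.null(cond$content)) cond$content$percent[1] else NA,
      coil = if (!is.null(cond$content)) cond$content$percent[2] else NA,
      turn = if (!is.null(cond$content)) cond$content$percent[3] else NA,
      height_nm = if (!is.null(cond$height)) cond$height$mean_nm else NA,
      length_nm = if (!is.null(cond$length)) cond$length$mean_length_nm else NA)
  }))
  utils::write.csv(rows, file.path(outdir, "kinetics_report.csv"),
                   row.names = FALSE)
  invisible(outdir)
}
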