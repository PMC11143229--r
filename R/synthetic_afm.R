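#' Synthetic rod-on-nanoribbon AFM images
#'
#' Emulates the AFM appearance of oligomers and short-rod SNFs adsorbed on
#' graphene nanoribbons: stripes of width 60 nm and period 120 nm at
#' 2.0 nm above the substrate (the apparent monolayer-plus-residue
#' thickness), objects drawn on the ribbons, Gaussian tip-convolution blur
#' and white height noise. Object heights are pre-scaled by the analytic
#' blur attenuation of their footprint so the *apparent* post-blur peak
#' heights land on the preset values.
#'
#' Modes:
#' * `"height"`: objects at the preset apparent height (SD 0.2 nm);
#'   oligomer presets give round blobs, rod presets give rods.
#' * `"length"`: rods with apparent heights uniform in 3-4 nm and spine
#'   lengths log-normal with mean equal to the preset mean length (shape
#'   `sdlog = 0.4`).
#'
#' The drawn geometry (per-object positions, spine lengths, heights) is
#' kept in `metadata$objects` so measurements can be checked against the
#' generating truth.
#'
#' @param preset preset name or list from [stage_preset()].
#' @param mode `"height"` or `"length"`.
#' @param seed integer RNG seed; all draws are derived from it.
#' @param size image side in pixels (>= 256).
#' @param pixel_nm pixel size, nm/px (<= 4).
#' @param n_objects number of objects; `NULL` scales a default density
#'   with the image area. 0 gives blank ribbons.
#' @param ribbon_width_nm,ribbon_period_nm,ribbon_height_nm,ribbon_angle_deg
#'   stripe geometry (angle of the stripe normal, degrees).
#' @param rod_width_nm drawn rod width.
#' @param blob_radius_nm drawn oligomer blob radius.
#' @param blur_sigma_px tip-convolution blur sigma in pixels (0 disables).
#' @param noise_sd white height-noise SD in nm (0 disables).
#' @return `snf_afm_image` with generator provenance in `metadata`.
#' @export
make_afm_image <- function(preset, mode = c("height", "length"), seed = 1,
                           size = 512, pixel_nm = 2, n_objects = NULL,
                           ribbon_width_nm = 60, ribbon_period_nm = 120,
                           ribbon_height_nm = 2.0, ribbon_angle_deg = 0,
                           rod_width_nm = 16, blob_radius_nm = 10,
                           blur_sigma_px = 2, noise_sd = 0.1) {
  mode <- match.arg(mode)
  if (is.character(preset)) preset <- stage_preset(preset)
  if (size < 256) snf_abort("size must be >= 256 px", "domain")
  if (pixel_nm > 4) snf_abort("pixel size must be <= 4 nm/px", "domain")
  if (mode == "length" && is.na(preset$mean_length_nm))
    snf_abort(sprintf("preset '%s' has no printed mean length", preset$name),
              "unknown_preset")

  oligomer <- mode == "height" && preset$morphology == "oligomer"
  if (is.null(n_objects)) {
    dens <- if (oligomer) 60 else if (mode == "length") 70 else 40
    n_objects <- max(if (mode == "height" && !oligomer) 10L else 12L,
                     as.integer(round(dens * (size / 1024)^2)))
    if (mode == "height" && size >= 512) n_objects <- max(20L, n_objects)
  }

  period_px <- ribbon_period_nm / pixel_nm
  width_px <- ribbon_width_nm / pixel_nm
  th <- ribbon_angle_deg * pi / 180
  rowi <- matrix(seq_len(size), size, size)
  coli <- matrix(seq_len(size), size, size, byrow = TRUE)
  s <- coli * cos(th) + rowi * sin(th)
  ribbon <- (s %% period_px) < width_px
  m <- ifelse(ribbon, ribbon_height_nm, 0)

  att_ridge <- function(w_px, L_px, sig) {
    if (sig <= 0) return(1)
    erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
    erf(w_px / (2 * sqrt(2) * sig)) * erf(L_px / (2 * sqrt(2) * sig))
  }
  att_disk <- function(r_px, sig) {
    if (sig <= 0) return(1)
    1 - exp(-r_px^2 / (2 * sig^2))
  }

  objects <- with_seed(seed, {
    if (n_objects == 0) {
      obj <- data.frame()
    } else {
      w_px <- rod_width_nm / pixel_nm
      r_px <- blob_radius_nm / pixel_nm
      hts <- if (mode == "length") {
        stats::runif(n_objects, 3, 4)
      } else {
        stats::rnorm(n_objects, preset$height_nm, 0.2)
      }
      hts <- pmax(hts, 0.2)
      lens_px <- if (oligomer) {
        rep(0, n_objects)
      } else if (mode == "length") {
        stats::rlnorm(n_objects, log(preset$mean_length_nm) - 0.4^2 / 2,
                      0.4) / pixel_nm
      } else {
        stats::rlnorm(n_objects, log(40 / pixel_nm), 0.25)
      }
      angs <- stats::runif(n_objects, 0, pi)
      placed <- matrix(numeric(0), 0, 3)   # row, col, clearance radius
      pos <- matrix(NA_real_, n_objects, 2)
      margin <- ceiling(3 * blur_sigma_px) + 2
      for (i in seq_len(n_objects)) {
        rad <- if (oligomer) r_px else lens_px[i] / 2 + w_px
        ok <- FALSE
        for (try in 1:400) {
          rc <- stats::runif(2, margin + rad + 1, size - margin - rad - 1)
          sc <- rc[2] * cos(th) + rc[1] * sin(th)
          if ((sc %% period_px) >= width_px) next   # center must be on-ribbon
          if (nrow(placed) > 0) {
            dd <- sqrt((placed[, 1] - rc[1])^2 + (placed[, 2] - rc[2])^2)
            if (any(dd < placed[, 3] + rad + 2)) next
          }
          placed <- rbind(placed, c(rc, rad))
          pos[i, ] <- rc
          ok <- TRUE
          break
        }
        if (!ok)
          snf_abort("could not place objects without excessive overlap",
                    "density")
      }
      obj <- data.frame(row = pos[, 1], col = pos[, 2],
                        height_nm = hts,
                        length_nm = lens_px * pixel_nm,
                        angle = angs)
    }
    obj
  })

  w_px <- rod_width_nm / pixel_nm
  r_px <- blob_radius_nm / pixel_nm
  if (nrow(objects) > 0) {
    for (i in seq_len(nrow(objects))) {
      o <- objects[i, ]
      if (oligomer) {
        att <- att_disk(r_px, blur_sigma_px)
        rr <- max(1, floor(o$row - r_px - 2)):min(size, ceiling(o$row + r_px + 2))
        cc <- max(1, floor(o$col - r_px - 2)):min(size, ceiling(o$col + r_px + 2))
        sub_r <- matrix(rr, length(rr), length(cc))
        sub_c <- matrix(cc, length(rr), length(cc), byrow = TRUE)
        inside <- (sub_r - o$row)^2 + (sub_c - o$col)^2 <= r_px^2
        lvl <- ribbon_height_nm + o$height_nm / att
        m[rr, cc][inside] <- pmax(m[rr, cc][inside], lvl)
      } else {
        L_px <- o$length_nm / pixel_nm
        att <- att_ridge(w_px, L_px, blur_sigma_px)
        ux <- cos(o$angle); uy <- sin(o$angle)
        half <- L_px / 2
        ext <- half + w_px / 2 + 2
        rr <- max(1, floor(o$row - ext)):min(size, ceiling(o$row + ext))
        cc <- max(1, floor(o$col - ext)):min(size, ceiling(o$col + ext))
        sub_r <- matrix(rr, length(rr), length(cc))
        sub_c <- matrix(cc, length(rr), length(cc), byrow = TRUE)
        dx <- sub_c - o$col; dy <- sub_r - o$row
        tproj <- dx * ux + dy * uy
        d2 <- (dx - tproj * ux)^2 + (dy - tproj * uy)^2
        # rectangular footprint: the full-width-at-half-maximum extent of
        # the (blurred or sharp) ridge then equals the drawn length
        inside <- abs(tproj) <= half & d2 <= (w_px / 2)^2
        lvl <- ribbon_height_nm + o$height_nm / att
        m[rr, cc][inside] <- pmax(m[rr, cc][inside], lvl)
      }
    }
  }

  if (blur_sigma_px > 0) {
    brush <- EBImage::makeBrush(2 * ceiling(3 * blur_sigma_px) + 1,
                                shape = "Gaussian", sigma = blur_sigma_px)
    m <- EBImage::filter2(m, brush, boundary = "replicate")
  }
  if (noise_sd > 0) {
    m <- m + with_seed(seed + 104729L,
                       matrix(stats::rnorm(size * size, sd = noise_sd),
                              size, size))
  }

  afm_image(m, pixel_nm, metadata = list(
    generator = "make_afm_image", preset = preset$name, mode = mode,
    seed = seed, ribbon_width_nm = ribbon_width_nm,
    ribbon_period_nm = ribbon_period_nm,
    ribbon_height_nm = ribbon_height_nm,
    ribbon_angle_deg = ribbon_angle_deg,
    blur_sigma_px = blur_sigma_px, noise_sd = noise_sd,
    objects = objects))
}
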