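#' Detect graphene nanoribbons in an AFM height map
#'
#' Finds the dominant stripe periodicity from the 2-D power spectrum of the
#' height map (which also yields the stripe orientation, so rotated scans
#' need no pre-alignment), classifies pixels into substrate and ribbon
#' levels, and takes the graphene reference level as the modal height of
#' the on-ribbon pixels. Rod pixels are a small minority and do not move
#' the mode.
#'
#' @param img a `snf_afm_image` containing at least ~3 stripe periods.
#' @param significance minimum ratio of the fundamental spectral peak to
#'   the median non-DC power; below it a `no_ribbon` error is raised.
#' @return `snf_ribbon_mask`: logical on-ribbon mask, stripe `width_nm`,
#'   `period_nm`, `orientation_deg` (stripe normal), `graphene_level` (nm).
#' @export
detect_ribbons <- function(img, significance = 100) {
  stopifnot(inherits(img, "snf_afm_image"))
  m <- img$map
  P <- Mod(stats::fft(m - mean(m)))^2
  nr <- nrow(P); nc <- ncol(P)
  fr <- ((seq_len(nr) - 1 + nr %/% 2) %% nr - nr %/% 2) / nr
  fc <- ((seq_len(nc) - 1 + nc %/% 2) %% nc - nc %/% 2) / nc
  fmag <- sqrt(outer(fr^2, fc^2, `+`))
  cand <- fmag > 2 / min(nr, nc)   # exclude DC and image-scale trends
  med <- stats::median(P[cand])
  peak <- max(P[cand])
  if (med <= 0 || peak / med < significance)
    snf_abort("no stripe periodicity above significance threshold",
              "no_ribbon")
  idx <- which(cand & P == peak, arr.ind = TRUE)[1, ]
  f <- c(fr[idx[1]], fc[idx[2]])
  period_px <- 1 / sqrt(sum(f^2))
  orientation <- atan2(f[1], f[2]) * 180 / pi

  # two-level height classification: substrate vs graphene
  samp <- as.numeric(m)
  if (length(samp) > 5e4) samp <- samp[seq(1, length(samp), length.out = 5e4)]
  km <- stats::kmeans(samp, centers = sort(stats::quantile(samp, c(0.25, 0.75))))
  mid <- mean(sort(km$centers))
  mask <- m > mid
  duty <- mean(mask)
  d <- stats::density(m[mask], n = 1024)
  ref <- d$x[which.max(d$y)]

  structure(list(mask = mask,
                 width_nm = duty * period_px * img$pixel_nm,
                 period_nm = period_px * img$pixel_nm,
                 orientation_deg = orientation,
                 graphene_level = ref),
            class = "snf_ribbon_mask")
}

#' @export
print.snf_ribbon_mask <- function(x, ...) {
  cat(sprintf(
    "<snf_ribbon_mask: width %.1f nm, period %.1f nm, ref level %.2f nm>\n",
    x$width_nm, x$period_nm, x$graphene_level))
  invisible(x)
}

# --- Zhang-Suen morphological thinning on a 0/1 matrix -----------------

shift_mat <- function(m, dr, dc) {
  n <- matrix(0L, nrow(m), ncol(m))
  r1 <- max(1, 1 - dr); r2 <- min(nrow(m), nrow(m) - dr)
  c1 <- max(1, 1 - dc); c2 <- min(ncol(m), ncol(m) - dc)
  if (r1 > r2 || c1 > c2) return(n)
  n[r1:r2, c1:c2] <- m[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc)]
  n
}

thin_zhang_suen <- function(B) {
  B <- (B != 0) + 0L
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift_mat(B, -1, 0);  p3 <- shift_mat(B, -1, 1)
      p4 <- shift_mat(B, 0, 1);   p5 <- shift_mat(B, 1, 1)
      p6 <- shift_mat(B, 1, 0);   p7 <- shift_mat(B, 1, -1)
      p8 <- shift_mat(B, 0, -1);  p9 <- shift_mat(B, -1, -1)
      Bn <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1) {
        cond <- p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      del <- B == 1 & Bn >= 2 & Bn <= 6 & A == 1 & cond
      if (any(del)) {
        B[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  B
}

# longest geodesic path through a skeleton; returns ordered pixel coords
# and the path length in pixels (8-connected, diagonal steps sqrt(2))
skeleton_path <- function(skel) {
  px <- which(skel == 1, arr.ind = TRUE)
  k <- nrow(px)
  if (k == 0) return(list(coords = px, length_px = 0))
  if (k == 1) return(list(coords = px, length_px = 0))
  id <- matrix(0L, nrow(skel), ncol(skel))
  id[px] <- seq_len(k)
  edges <- NULL
  w <- NULL
  for (off in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    nb <- shift_mat(id, off[1], off[2])
    hit <- id > 0 & nb > 0
    if (any(hit)) {
      edges <- rbind(edges, cbind(id[hit], nb[hit]))
      w <- c(w, rep(sqrt(sum(off^2)), sum(hit)))
    }
  }
  if (is.null(edges)) return(list(coords = px[1, , drop = FALSE], length_px = 0))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- w
  if (igraph::vcount(g) < k) g <- igraph::add_vertices(g, k - igraph::vcount(g))
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  vs <- which(comp$membership == main)
  # double sweep: farthest vertex from an arbitrary one, then its farthest
  d1 <- igraph::distances(g, v = vs[1], to = vs)[1, ]
  u <- vs[which.max(d1)]
  d2 <- igraph::distances(g, v = u, to = vs)[1, ]
  v <- vs[which.max(d2)]
  pathv <- as.integer(igraph::shortest_paths(g, from = u, to = v,
                                             output = "vpath")$vpath[[1]])
  list(coords = px[pathv, , drop = FALSE], length_px = max(d2))
}

path_step_lengths <- function(coords) {
  if (nrow(coords) < 2) return(numeric(0))
  # moving-average smoothing of the pixel path removes the staircase bias
  # of digitized diagonal lines (up to ~8% at 22.5 deg) before summation
  if (nrow(coords) >= 5) {
    sm <- apply(coords, 2, function(v) {
      f <- stats::filter(v, rep(1 / 5, 5), sides = 2)
      f[1:2] <- v[1:2]
      f[(length(v) - 1):length(v)] <- v[(length(v) - 1):length(v)]
      as.numeric(f)
    })
    coords <- sm
  }
  sqrt(rowSums((coords[-1, , drop = FALSE] -
                  coords[-nrow(coords), , drop = FALSE])^2))
}

#' Segment rod-like objects from an AFM height map
#'
#' Thresholds the map at the graphene reference level plus `min_height`,
#' labels connected components, thins each component to its morphological
#' skeleton and measures the geodesic skeleton length. The reported rod
#' length is measured between the half-maximum crossings of the height
#' profile along the skeleton axis: the geodesic path is clipped where it
#' falls below half the rod's peak prominence and each endpoint is then
#' extended along the local axis direction until the height drops below
#' half maximum. This "length at half maximum" is insensitive to the
#' absolute threshold and unbiased by thinning erosion at stubby rod
#' ends. Peak heights are read from a lightly smoothed
#' map (Gaussian, `smooth_px`) so single-pixel noise does not inflate the
#' maxima.
#'
#' @param img a `snf_afm_image`.
#' @param mask a `snf_ribbon_mask` from [detect_ribbons()], or `NULL` to
#'   reference heights against the modal height of the whole image.
#' @param min_height segmentation threshold above the graphene level, nm;
#'   should exceed ~3x the image noise SD.
#' @param min_px discard components smaller than this many pixels.
#' @param smooth_px Gaussian sigma (px) of the measurement smoothing;
#'   0 disables it.
#' @return data.frame of class `snf_rod_segments`, one row per segment:
#'   `length_nm`, `peak_height_nm`, `mean_height_nm`, `orientation_deg`,
#'   `n_px`, `row`, `col` (centroid). Attributes record the reference
#'   level, threshold and pixel size. Empty segmentation gives zero rows.
#' @export
segment_rods <- function(img, mask = NULL, min_height = 1,
                         min_px = 10, smooth_px = 1) {
  stopifnot(inherits(img, "snf_afm_image"))
  m <- img$map
  if (is.null(mask)) {
    d <- stats::density(m, n = 1024)
    ref <- d$x[which.max(d$y)]
  } else {
    stopifnot(inherits(mask, "snf_ribbon_mask"))
    ref <- mask$graphene_level
  }
  ms <- if (smooth_px > 0) {
    brush <- EBImage::makeBrush(2 * ceiling(3 * smooth_px) + 1,
                                shape = "Gaussian", sigma = smooth_px)
    EBImage::filter2(m, brush, boundary = "replicate")
  } else m
  bw <- m > ref + min_height
  lab <- EBImage::bwlabel(bw)
  n <- max(lab)
  rows <- list()
  for (i in seq_len(n)) {
    pix <- which(lab == i, arr.ind = TRUE)
    if (nrow(pix) < min_px) next
    r0 <- max(1, min(pix[, 1]) - 1); r1 <- min(nrow(m), max(pix[, 1]) + 1)
    c0 <- max(1, min(pix[, 2]) - 1); c1 <- min(ncol(m), max(pix[, 2]) + 1)
    sub <- (lab[r0:r1, c0:c1] == i) + 0L
    peak <- max(ms[pix]) - ref
    sk <- thin_zhang_suen(sub)
    sp <- skeleton_path(sk)
    len_px <- 0
    if (nrow(sp$coords) >= 1) {
      co <- sp$coords
      co[, 1] <- co[, 1] + r0 - 1
      co[, 2] <- co[, 2] + c0 - 1
      hpath <- ms[co] - ref
      ok <- which(hpath >= peak / 2)
      if (length(ok) == 0) ok <- which.max(hpath)
      co <- co[min(ok):max(ok), , drop = FALSE]
      len_px <- sum(path_step_lengths(co))
      half_lvl <- ref + peak / 2
      cen_px <- colMeans(pix)
      pax <- if (nrow(pix) > 2) eigen(stats::cov(pix))$vectors[, 1]
             else c(1, 0)
      if (nrow(co) >= 6) {
        # extend both ends along the local path axis to the half-max
        # contour, recovering the extent eroded by thinning
        for (end in c(1, 2)) {
          pts <- if (end == 1) co[seq_len(min(10, nrow(co))), , drop = FALSE]
                 else co[nrow(co):max(1, nrow(co) - 9), , drop = FALSE]
          v <- stats::prcomp(pts)$rotation[, 1]
          s <- sum((pts[1, ] - pts[nrow(pts), ]) * v)
          dirv <- v * if (s >= 0) 1 else -1
          pos <- pts[1, ]
          travelled <- 0
          while (travelled < 60) {
            nxt <- pos + 0.5 * dirv
            ri <- round(nxt[1]); ci <- round(nxt[2])
            if (ri < 1 || ci < 1 || ri > nrow(m) || ci > ncol(m)) break
            if (ms[ri, ci] < half_lvl) break
            pos <- nxt
            travelled <- travelled + 0.5
          }
          len_px <- len_px + travelled
        }
      } else {
        # degenerate skeleton (stubby object, or thinning collapse on
        # near-45-degree rods): extent of half-max pixels projected on
        # the component principal axis
        hm <- pix[ms[pix] >= half_lvl, , drop = FALSE]
        if (nrow(hm) >= 2) {
          proj <- (hm[, 1] - cen_px[1]) * pax[1] + (hm[, 2] - cen_px[2]) * pax[2]
          len_px <- diff(range(proj))
        }
      }
    }
    cen <- colMeans(pix)
    or_deg <- if (nrow(pix) > 2) {
      ev <- eigen(stats::cov(pix))$vectors[, 1]
      (atan2(ev[2], ev[1]) * 180 / pi) %% 180
    } else 0
    rows[[length(rows) + 1L]] <- data.frame(
      length_nm = len_px * img$pixel_nm,
      peak_height_nm = peak,
      mean_height_nm = mean(m[pix]) - ref,
      orientation_deg = or_deg,
      n_px = nrow(pix),
      row = cen[1], col = cen[2])
  }
  out <- if (length(rows) == 0) {
    data.frame(length_nm = numeric(0), peak_height_nm = numeric(0),
               mean_height_nm = numeric(0), orientation_deg = numeric(0),
               n_px = integer(0), row = numeric(0), col = numeric(0))
  } else do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("snf_rod_segments", "data.frame"),
            graphene_level = ref, min_height = min_height,
            pixel_nm = img$pixel_nm,
            height_definition = "per-rod peak above graphene reference")
}

#' Per-position rod heights with SEM
#'
#' Mirrors the practice of collecting heights from several image positions
#' and reporting mean +/- SEM across positions. Each segment is assigned to
#' the position containing its centroid; positions with no segment are
#' excluded with a warning.
#'
#' @param segments a `snf_rod_segments` data.frame.
#' @param positions list of regions `c(row_min, row_max, col_min, col_max)`
#'   in pixels.
#' @return `snf_morphology_stats` with `per_position` means, overall
#'   `mean_nm` and `sem_nm`.
#' @export
measure_heights <- function(segments, positions) {
  stopifnot(inherits(segments, "snf_rod_segments"), length(positions) >= 1)
  per <- vapply(positions, function(p) {
    inside <- segments$row >= p[1] & segments$row <= p[2] &
      segments$col >= p[3] & segments$col <= p[4]
    if (!any(inside)) return(NA_real_)
    mean(segments$peak_height_nm[inside])
  }, numeric(1))
  if (all(is.na(per)))
    snf_abort("no position contains any segment", "degenerate_input")
  if (any(is.na(per)))
    snf_warn(sprintf("%d position(s) with zero segments excluded",
                     sum(is.na(per))), "empty_position")
  per <- per[!is.na(per)]
  structure(list(per_position = per, mean_nm = mean(per), sem_nm = sem(per),
                 n_positions = length(per),
                 height_definition = attr(segments, "height_definition")),
            class = "snf_morphology_stats")
}

#' Band-filtered rod length distribution
#'
#' Retains segments whose peak height lies inside `height_band` (endpoints
#' included) and summarizes their skeleton lengths with a 10-nm-bin
#' histogram, matching the practice of reporting length statistics for
#' rods of 3-4 nm apparent height.
#'
#' @param segments a `snf_rod_segments` data.frame.
#' @param height_band `c(lo, hi)` in nm, lo < hi.
#' @param bin_nm histogram bin width in nm.
#' @return `snf_morphology_stats` with `lengths_nm`, `mean_length_nm`
#'   (`NaN` when nothing falls in the band, with `empty = TRUE`),
#'   histogram `breaks`/`counts`, and the band used.
#' @export
length_distribution <- function(segments, height_band = c(3, 4), bin_nm = 10) {
  stopifnot(inherits(segments, "snf_rod_segments"))
  if (!(height_band[1] < height_band[2]))
    snf_abort("height band lo must be < hi", "domain")
  keep <- segments$peak_height_nm >= height_band[1] &
    segments$peak_height_nm <= height_band[2]
  lens <- segments$length_nm[keep]
  if (length(lens) == 0) {
    return(structure(list(lengths_nm = numeric(0), mean_length_nm = NaN,
                          breaks = numeric(0), counts = integer(0),
                          height_band = height_band, empty = TRUE),
                     class = "snf_morphology_stats"))
  }
  breaks <- seq(0, (max(lens) %/% bin_nm + 1) * bin_nm, by = bin_nm)
  h <- graphics::hist(lens, breaks = breaks, plot = FALSE)
  structure(list(lengths_nm = lens, mean_length_nm = mean(lens),
                 breaks = h$breaks, counts = h$counts,
                 height_band = height_band, empty = FALSE),
            class = "snf_morphology_stats")
}

#' @export
print.snf_morphology_stats <- function(x, ...) {
  cat("<snf_morphology_stats>\n")
  if (!is.null(x$mean_nm))
    cat(sprintf("  height: %.2f +/- %.2f nm over %d positions\n",
                x$mean_nm, x$sem_nm, x$n_positions))
  if (!is.null(x$mean_length_nm))
    cat(sprintf("  length: mean %.1f nm (n = %d, band %g-%g nm)\n",
                x$mean_length_nm, length(x$lengths_nm),
                x$height_band[1], x$height_band[2]))
  invisible(x)
}
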