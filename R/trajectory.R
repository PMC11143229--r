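#' Intermolecular contact number
#'
#' Counts unordered intermolecular residue pairs whose C-alpha distance is
#' strictly below the cutoff (default 10 Angstrom), over every distinct
#' chain pair. With a list of chain sets (replicas) the per-replica counts
#' are aggregated as mean +/- SEM.
#'
#' @param x a `snf_chain_set`, or a list of them (replicas).
#' @param cutoff C-alpha distance cutoff in Angstrom; pairs at exactly the
#'   cutoff are not counted.
#' @return `snf_contact_result` with `per_replica`, `mean`, `sem`,
#'   `cutoff`, and `pair_rule = "all distinct chain pairs"`.
#' @export
contact_number <- function(x, cutoff = 10) {
  sets <- if (inherits(x, "snf_chain_set")) list(x) else x
  stopifnot(all(vapply(sets, inherits, TRUE, "snf_chain_set")))
  counts <- vapply(sets, function(cs) {
    if (n_chains(cs) < 2)
      snf_abort("contact_number needs at least two chains", "needs_two_chains")
    cas <- lapply(cs$chains, `[[`, "ca")
    total <- 0L
    for (i in seq_along(cas)[-length(cas)]) {
      for (j in (i + 1):length(cas)) {
        a <- cas[[i]]; b <- cas[[j]]
        d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
        total <- total + sum(d2 < cutoff^2)
      }
    }
    as.integer(total)
  }, integer(1))
  structure(list(per_replica = counts, mean = mean(counts),
                 sem = sem(counts), cutoff = cutoff,
                 pair_rule = "all distinct chain pairs"),
            class = "snf_contact_result")
}

#' @export
print.snf_contact_result <- function(x, ...) {
  cat(sprintf("<contacts: N = %.1f%s over %d replica(s), cutoff %g A>\n",
              x$mean,
              if (is.finite(x$sem %||% NA)) sprintf(" +/- %.1f", x$sem) else "",
              length(x$per_replica), x$cutoff))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hydrogen-bond criteria
#'
#' Geometric criteria: donor-acceptor distance <= `max_da_nm` (0.35 nm)
#' and hydrogen-donor-acceptor angle <= `max_angle_deg` (30 degrees),
#' both inclusive.
#'
#' @param max_da_nm maximum donor-acceptor distance in nm.
#' @param max_angle_deg maximum H-D-A angle in degrees.
#' @return list of class `snf_hbond_criteria`.
#' @export
hbond_criteria <- function(max_da_nm = 0.35, max_angle_deg = 30) {
  if (max_da_nm <= 0 || max_angle_deg <= 0)
    snf_abort("criteria must be positive", "domain")
  structure(list(max_da_nm = max_da_nm, max_angle_deg = max_angle_deg),
            class = "snf_hbond_criteria")
}

#' Find hydrogen bonds
#'
#' Enumerates donor (amide N, with its H) / acceptor (carbonyl O) residue
#' pairs satisfying both inclusive criteria. Coordinates are in Angstrom;
#' the distance criterion is converted from nm.
#'
#' @param chains a `snf_chain_set` whose residues carry `n`, `h` and `o`
#'   coordinates.
#' @param criteria a [hbond_criteria()].
#' @return data.frame with donor/acceptor chain and residue, distance (A)
#'   and angle (degrees); zero rows when none qualify.
#' @export
find_hbonds <- function(chains, criteria = hbond_criteria()) {
  stopifnot(inherits(chains, "snf_chain_set"))
  don <- list(); acc <- list()
  for (ch in names(chains$chains)) {
    e <- chains$chains[[ch]]
    for (role in c("n", "h", "o")) {
      if (is.null(e[[role]]))
        snf_abort(sprintf("chain %s lacks '%s' coordinates needed for H-bonds",
                          ch, role), "capability")
    }
    ok_d <- which(rowSums(is.na(e$n)) == 0 & rowSums(is.na(e$h)) == 0)
    ok_a <- which(rowSums(is.na(e$o)) == 0)
    if (length(ok_d))
      don[[ch]] <- data.frame(chain = ch, res = ok_d,
                              nx = e$n[ok_d, 1], ny = e$n[ok_d, 2], nz = e$n[ok_d, 3],
                              hx = e$h[ok_d, 1], hy = e$h[ok_d, 2], hz = e$h[ok_d, 3])
    if (length(ok_a))
      acc[[ch]] <- data.frame(chain = ch, res = ok_a,
                              ox = e$o[ok_a, 1], oy = e$o[ok_a, 2], oz = e$o[ok_a, 3])
  }
  don <- do.call(rbind, don); acc <- do.call(rbind, acc)
  out <- data.frame(donor_chain = character(0), donor_res = integer(0),
                    acceptor_chain = character(0), acceptor_res = integer(0),
                    dist_A = numeric(0), angle_deg = numeric(0))
  if (is.null(don) || is.null(acc)) return(out)
  dmax <- criteria$max_da_nm * 10
  for (i in seq_len(nrow(don))) {
    same <- acc$chain == don$chain[i] & acc$res == don$res[i]
    dx <- acc$ox - don$nx[i]; dy <- acc$oy - don$ny[i]; dz <- acc$oz - don$nz[i]
    dda <- sqrt(dx^2 + dy^2 + dz^2)
    hx <- don$hx[i] - don$nx[i]; hy <- don$hy[i] - don$ny[i]; hz <- don$hz[i] - don$nz[i]
    hn <- sqrt(hx^2 + hy^2 + hz^2)
    cosang <- (dx * hx + dy * hy + dz * hz) / (dda * hn)
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    hit <- !same & dda <= dmax + 1e-12 & ang <= criteria$max_angle_deg + 1e-9
    if (any(hit)) {
      out <- rbind(out, data.frame(
        donor_chain = don$chain[i], donor_res = don$res[i],
        acceptor_chain = acc$chain[hit], acceptor_res = acc$res[hit],
        dist_A = dda[hit], angle_deg = ang[hit]))
    }
  }
  rownames(out) <- NULL
  out
}

#' Assign beta-strand residues from C-alpha geometry
#'
#' A simplified strand assignment applicable to coarse-grained three-bead
#' chains as well as all-atom backbones. Residue i is "extended" when
#' |CA_i - CA_(i+2)| lies in 5.9-7.2 Angstrom; maximal runs of at least 3
#' consecutive extended residues (covering residues i .. i+run+1) form
#' candidate strand runs. A run residue is labelled `strand` only if its
#' CA lies within 5.5 Angstrom of a CA belonging to a *different* run
#' (the ladder condition -- an isolated extended chain is not a sheet).
#'
#' @param chains a `snf_chain_set`.
#' @return `snf_strand_assignment`: per-chain label vectors
#'   (`strand`/`other`), per-chain and overall beta fractions, and the
#'   run table used by [strand_axis_alignment()].
#' @export
assign_strands <- function(chains) {
  stopifnot(inherits(chains, "snf_chain_set"))
  runs <- list()          # each: chain, residue indices
  labels <- list()
  for (ch in names(chains$chains)) {
    ca <- chains$chains[[ch]]$ca
    n <- nrow(ca)
    labels[[ch]] <- rep("other", n)
    if (n < 5) {
      snf_warn(sprintf("chain %s has < 5 residues; labelled all other", ch),
               "short_chain")
      next
    }
    d13 <- sqrt(rowSums((ca[seq_len(n - 2) + 2, , drop = FALSE] -
                           ca[seq_len(n - 2), , drop = FALSE])^2))
    ext <- d13 >= 5.9 & d13 <= 7.2
    r <- rle(ext)
    pos <- cumsum(c(1, r$lengths))
    for (k in seq_along(r$values)) {
      if (r$values[k] && r$lengths[k] >= 3) {
        res <- pos[k]:(pos[k] + r$lengths[k] + 1)   # residues spanned
        runs[[length(runs) + 1L]] <- list(chain = ch, res = res)
      }
    }
  }
  # ladder condition against residues of other runs
  run_ca <- lapply(runs, function(r) chains$chains[[r$chain]]$ca[r$res, , drop = FALSE])
  for (k in seq_along(runs)) {
    others <- do.call(rbind, run_ca[-k])
    if (is.null(others) || nrow(others) == 0) next
    a <- run_ca[[k]]
    d2 <- outer(rowSums(a^2), rowSums(others^2), `+`) - 2 * tcrossprod(a, others)
    paired <- apply(d2, 1, min) <= 5.5^2
    lad <- runs[[k]]$res[paired]
    labels[[runs[[k]]$chain]][lad] <- "strand"
  }
  per_chain <- vapply(labels, function(l) mean(l == "strand"), numeric(1))
  total <- sum(vapply(labels, length, 0L))
  overall <- sum(vapply(labels, function(l) sum(l == "strand"), 0L)) / total
  structure(list(labels = labels, runs = runs,
                 beta_fraction = per_chain, overall_beta = overall),
            class = "snf_strand_assignment")
}

#' @export
print.snf_strand_assignment <- function(x, ...) {
  cat(sprintf("<strand assignment: %d run(s), overall beta fraction %.2f>\n",
              length(x$runs), x$overall_beta))
  invisible(x)
}

#' Nematic order parameter P2
#'
#' `P2 = mean((3 cos^2 theta - 1) / 2)` over the acute angles between each
#' axis and the reference; 1 for parallel, 0 for isotropic, -0.5 for
#' perpendicular. Axes are headless: the sign of each vector is
#' irrelevant.
#'
#' @param axes n x 3 matrix of axis vectors (not necessarily unit).
#' @param reference reference axis vector.
#' @return numeric P2 in \[-0.5, 1\].
#' @export
p2_order_parameter <- function(axes, reference) {
  axes <- matrix(axes, ncol = 3)
  nr <- sqrt(rowSums(axes^2))
  ref <- reference / sqrt(sum(reference^2))
  cost <- abs(axes %*% ref) / nr
  mean((3 * cost^2 - 1) / 2)
}

#' Strand-axis alignment against the fibril elongation axis
#'
#' Each strand run's axis is the principal direction of its CA
#' coordinates; the fibril elongation axis is the principal direction of
#' all strand-labelled CAs pooled. Reports per-run acute angles to the
#' fibril axis, their mean, and the nematic order parameter P2.
#'
#' @param chains a `snf_chain_set`.
#' @param assignment result of [assign_strands()]; computed when `NULL`.
#' @return `snf_alignment_stats` with `axes`, `fibril_axis`,
#'   `angles_deg`, `mean_angle_deg`, `p2`.
#' @export
strand_axis_alignment <- function(chains, assignment = NULL) {
  stopifnot(inherits(chains, "snf_chain_set"))
  if (is.null(assignment)) assignment <- assign_strands(chains)
  keep <- vapply(assignment$runs, function(r) {
    sum(assignment$labels[[r$chain]][r$res] == "strand") >= 3
  }, logical(1))
  runs <- assignment$runs[keep]
  if (length(runs) == 0)
    snf_abort("no strand run of >= 3 residues", "no_strand")
  axes <- t(vapply(runs, function(r) {
    ca <- chains$chains[[r$chain]]$ca[r$res, , drop = FALSE]
    stats::prcomp(ca)$rotation[, 1]
  }, numeric(3)))
  all_ca <- do.call(rbind, lapply(runs, function(r)
    chains$chains[[r$chain]]$ca[r$res, , drop = FALSE]))
  fib <- stats::prcomp(all_ca)$rotation[, 1]
  cost <- abs(axes %*% fib) / sqrt(rowSums(axes^2))
  angles <- acos(pmin(pmax(cost, 0), 1)) * 180 / pi
  structure(list(axes = axes, fibril_axis = as.numeric(fib),
                 angles_deg = as.numeric(angles),
                 mean_angle_deg = mean(angles),
                 p2 = p2_order_parameter(axes, fib)),
            class = "snf_alignment_stats")
}

#' @export
print.snf_alignment_stats <- function(x, ...) {
  cat(sprintf("<alignment: %d strands, mean angle %.1f deg, P2 = %.3f>\n",
              nrow(x$axes), x$mean_angle_deg, x$p2))
  invisible(x)
}
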