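#' Synthetic multi-chain configurations
#'
#' Generates chain sets emulating the end states of assembly simulations:
#'
#' * `"fibril"`: extended strands on a lattice -- intra-strand CA spacing
#'   3.4 A along a common axis, 4.8 A between strands within a sheet,
#'   10 A between sheets -- the ordered beta-sheet geometry.
#' * `"aggregate"`: compact random-walk chains packed around a common
#'   center, in mutual contact but orientationally disordered.
#' * `"dispersed"`: the same walks but placed on a wide lattice with
#'   > 20 A clearance between chains, so no intermolecular contacts.
#'
#' All coordinates receive seeded Gaussian jitter (SD `jitter_sd`).
#'
#' @param arrangement `"fibril"`, `"aggregate"` or `"dispersed"`.
#' @param n_chains number of chains (>= 1).
#' @param n_res residues per chain (>= 5).
#' @param seed integer RNG seed.
#' @param jitter_sd coordinate jitter SD in Angstrom.
#' @return a `snf_chain_set`.
#' @export
make_chain_config <- function(arrangement = c("fibril", "aggregate", "dispersed"),
                              n_chains = 4, n_res = 10, seed = 1,
                              jitter_sd = 0.3) {
  arrangement <- match.arg(arrangement)
  if (n_chains < 1) snf_abort("n_chains must be >= 1", "domain")
  if (n_res < 5) snf_abort("n_res must be >= 5", "domain")
  with_seed(seed, {
    chains <- vector("list", n_chains)
    if (arrangement == "fibril") {
      per_sheet <- max(1, ceiling(sqrt(n_chains)))
      for (k in seq_len(n_chains)) {
        sheet <- (k - 1) %/% per_sheet
        strand <- (k - 1) %% per_sheet
        ca <- cbind(3.4 * (seq_len(n_res) - 1), 4.8 * strand, 10 * sheet)
        chains[[k]] <- list(ca = ca + matrix(stats::rnorm(3 * n_res,
                                                          sd = jitter_sd),
                                             ncol = 3))
      }
    } else {
      walk <- function() {
        # compact self-avoiding-ish walk confined to a sphere
        R <- 2.2 * n_res^0.5
        ca <- matrix(0, n_res, 3)
        for (i in 2:n_res) {
          repeat {
            u <- stats::rnorm(3)
            cand <- ca[i - 1, ] + 3.8 * u / sqrt(sum(u^2))
            if (sqrt(sum(cand^2)) <= R) break
          }
          ca[i, ] <- cand
        }
        ca
      }
      ws <- replicate(n_chains, walk(), simplify = FALSE)
      if (arrangement == "aggregate") {
        for (k in seq_len(n_chains)) {
          off <- stats::rnorm(3, sd = 4)
          chains[[k]] <- list(ca = ws[[k]] +
                                matrix(off, n_res, 3, byrow = TRUE) +
                                matrix(stats::rnorm(3 * n_res, sd = jitter_sd),
                                       ncol = 3))
        }
      } else {
        ext <- max(vapply(ws, function(w) max(sqrt(rowSums(w^2))), 0))
        spacing <- 2 * ext + 25
        side <- ceiling(n_chains^(1 / 3))
        for (k in seq_len(n_chains)) {
          i <- (k - 1) %% side
          j <- ((k - 1) %/% side) %% side
          l <- (k - 1) %/% (side * side)
          off <- spacing * c(i, j, l)
          chains[[k]] <- list(ca = ws[[k]] +
                                matrix(off, n_res, 3, byrow = TRUE) +
                                matrix(stats::rnorm(3 * n_res, sd = jitter_sd),
                                       ncol = 3))
        }
      }
    }
    names(chains) <- LETTERS[(seq_len(n_chains) - 1) %% 26 + 1]
    if (n_chains > 26)
      names(chains) <- paste0(names(chains), rep(seq_len(ceiling(n_chains / 26)),
                                                 each = 26)[seq_len(n_chains)])
    chain_set(chains)
  })
}
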