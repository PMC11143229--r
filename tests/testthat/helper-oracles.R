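# Independent oracles and geometry builders shared across tests.

# O(n^2) brute-force contact count with explicit loops; deliberately
# naive and independent of the package implementation.
brute_force_contacts <- function(cs, cutoff = 10) {
  nm <- names(cs$chains)
  tot <- 0L
  for (i in seq_along(nm)) for (j in seq_along(nm)) if (i < j) {
    a <- cs$chains[[i]]$ca
    b <- cs$chains[[j]]$ca
    for (p in seq_len(nrow(a))) for (q in seq_len(nrow(b))) {
      if (sqrt(sum((a[p, ] - b[q, ])^2)) < cutoff) tot <- tot + 1L
    }
  }
  tot
}

# ideal antiparallel-free ladder: extended strands along x, 3.4 A CA
# spacing, given inter-strand offsets (A)
ideal_ladder <- function(n_res = 10, strand_offsets = list(c(0, 0, 0),
                                                           c(0, 4.8, 0))) {
  chains <- lapply(strand_offsets, function(off) {
    list(ca = cbind(3.4 * (seq_len(n_res) - 1) + off[1],
                    rep(off[2], n_res), rep(off[3], n_res)))
  })
  names(chains) <- LETTERS[seq_along(chains)]
  chain_set(chains)
}

# compact helix-like chain: |CA_i - CA_(i+2)| ~ 5.4 A (alpha geometry)
helix_chain <- function(n_res = 12) {
  t <- seq_len(n_res)
  r <- 2.3
  ca <- cbind(r * cos(100 * pi / 180 * t), r * sin(100 * pi / 180 * t),
              1.5 * t)
  chain_set(list(A = list(ca = ca)))
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rotate_chain_set <- function(cs, R, shift = c(0, 0, 0)) {
  cs$chains <- lapply(cs$chains, function(e) {
    for (role in names(e)) {
      e[[role]] <- sweep(e[[role]] %*% t(R), 2, -shift)
    }
    e
  })
  cs
}

# three-Gaussian amide band from explicit parameters
gauss3_band <- function(mu, sigma, h, grid = seq(1600, 1700, by = 1)) {
  v <- h[1] * exp(-(grid - mu[1])^2 / (2 * sigma[1]^2)) +
    h[2] * exp(-(grid - mu[2])^2 / (2 * sigma[2]^2)) +
    h[3] * exp(-(grid - mu[3])^2 / (2 * sigma[3]^2))
  spectrum(grid, v, "delta_extinction")
}
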