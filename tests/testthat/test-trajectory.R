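test_that("contact number matches the brute-force oracle on random instances", {
  set.seed(11)
  for (rep in 1:200) {
    nch <- sample(2:4, 1)
    nres <- sample(5:15, 1)
    arr <- sample(c("aggregate", "fibril", "dispersed"), 1)
    cs <- make_chain_config(arr, nch, nres, seed = 5000 + rep)
    expect_identical(contact_number(cs)$per_replica[1],
                     brute_force_contacts(cs))
  }
})

test_that("contact counting honours the strict cutoff and chain symmetry", {
  two <- chain_set(list(
    A = list(ca = cbind(c(0, 3.8, 7.6), 0, 0)),
    B = list(ca = cbind(c(0, 3.8, 7.6), 12, 0))))
  expect_equal(contact_number(two)$mean, 0)   # min distance 12 A

  close3 <- chain_set(list(
    A = list(ca = cbind(c(0, 3.8, 7.6), 0, 0)),
    B = list(ca = cbind(c(0, 3.8, 7.6), 4, 0))))
  expect_equal(contact_number(close3)$mean, 9)  # all 9 pairs < 10 A

  # exactly at the cutoff is not a contact
  pair <- chain_set(list(A = list(ca = cbind(c(0, 100, 200), 0, 0)),
                         B = list(ca = cbind(c(10, 300, 400), 0, 0))))
  expect_equal(contact_number(pair, cutoff = 10)$mean, 0)

  # label swap and rigid motion leave the count unchanged
  swapped <- chain_set(rev(close3$chains))
  expect_equal(contact_number(swapped)$mean, 9)
  R <- random_rotation(3)
  rot <- rotate_chain_set(close3, R, shift = c(5, -2, 7))
  expect_equal(contact_number(rot)$mean, 9)

  one <- chain_set(list(A = list(ca = cbind(c(0, 3.8, 7.6), 0, 0))))
  expect_error(contact_number(one), class = "snf_error_needs_two_chains")
})

test_that("contact number is non-increasing as the cutoff shrinks", {
  cs <- make_chain_config("aggregate", 4, 12, seed = 9)
  cuts <- c(12, 10, 8, 6, 4)
  ns <- vapply(cuts, function(cc) contact_number(cs, cc)$mean, numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("replica aggregation reports mean and SEM over configurations", {
  reps <- lapply(1:5, function(s) make_chain_config("aggregate", 3, 10, seed = s))
  cr <- contact_number(reps)
  expect_equal(length(cr$per_replica), 5)
  expect_equal(cr$mean, mean(cr$per_replica))
  expect_equal(cr$sem, sd(cr$per_replica) / sqrt(5))
})

test_that("hydrogen-bond criteria are inclusive at both boundaries", {
  mk <- function(d_na, angle_deg) {
    # donor N at origin, H along +x; acceptor O at distance d, angle theta
    th <- angle_deg * pi / 180
    chain_set(list(
      A = list(ca = cbind(c(0, 3.8, 7.6), 0, 0),
               n = cbind(c(0, 500, 600), 0, 0),
               h = cbind(c(1, 501, 601), 0, 0),
               o = cbind(c(900, 910, 920), 0, 0)),
      B = list(ca = cbind(c(0, 3.8, 7.6), 700, 0),
               n = cbind(c(0, 3.8, 7.6), 700, 0),
               h = cbind(c(1, 4.8, 8.6), 700, 0),
               o = cbind(c(d_na * cos(th), 950, 960),
                         c(d_na * sin(th), 0, 0), 0))))
  }
  expect_equal(nrow(find_hbonds(mk(2.9, 0))), 1)     # linear, short
  expect_equal(nrow(find_hbonds(mk(3.6, 0))), 0)     # beyond 0.35 nm
  expect_equal(nrow(find_hbonds(mk(3.5, 30))), 1)    # both boundaries inclusive
  expect_equal(nrow(find_hbonds(mk(3.0, 30.5))), 0)  # just past the angle

  noH <- chain_set(list(A = list(ca = cbind(c(0, 3.8, 7.6), 0, 0),
                                 n = cbind(c(0, 3.8, 7.6), 0, 0),
                                 o = cbind(c(0, 3.8, 7.6), 1, 0))))
  expect_error(find_hbonds(noH), class = "snf_error_capability")
})

test_that("strand assignment requires extended geometry plus a ladder partner", {
  lad <- ideal_ladder(10)
  asg <- assign_strands(lad)
  expect_equal(asg$beta_fraction, c(A = 1, B = 1))

  # compact helix-like geometry: |CA_i - CA_(i+2)| ~ 5.4 A -> no strands
  hx <- helix_chain(12)
  d13 <- sqrt(sum((hx$chains$A$ca[3, ] - hx$chains$A$ca[1, ])^2))
  expect_lt(d13, 5.9)
  expect_warning(regexp = NA, {
    asg_h <- assign_strands(hx)
  })
  expect_equal(asg_h$overall_beta, 0)

  # an isolated extended chain has no ladder partner
  iso <- chain_set(list(A = list(ca = cbind(3.4 * (0:9), 0, 0))))
  expect_equal(assign_strands(iso)$overall_beta, 0)

  shorty <- chain_set(list(A = list(ca = cbind(3.4 * (0:3), 0, 0)),
                           B = list(ca = cbind(3.4 * (0:9), 4.8, 0))))
  expect_warning(asg_s <- assign_strands(shorty),
                 class = "snf_warning_short_chain")
  expect_equal(asg_s$beta_fraction[["A"]], 0)
})

test_that("strand axes align with the fibril axis in ideal geometry", {
  lad <- ideal_ladder(10, list(c(0, 0, 0), c(0, 4.8, 0), c(0, 0, 10),
                               c(0, 4.8, 10)))
  al <- strand_axis_alignment(lad)
  expect_equal(al$p2, 1, tolerance = 1e-9)
  expect_equal(al$mean_angle_deg, 0, tolerance = 1e-6)

  expect_error(strand_axis_alignment(helix_chain(12)),
               class = "snf_error_no_strand")
})

test_that("P2 reaches its closed-form limits and isotropic zero", {
  ref <- c(0, 0, 1)
  par3 <- matrix(rep(c(0, 0, 1), 5), ncol = 3, byrow = TRUE)
  expect_equal(p2_order_parameter(par3, ref), 1)
  perp <- matrix(c(1, 0, 0, 0, 1, 0, 1, 1, 0), ncol = 3, byrow = TRUE)
  expect_equal(p2_order_parameter(perp, ref), -0.5)

  set.seed(13)
  iso <- matrix(rnorm(3e5), ncol = 3)
  expect_equal(p2_order_parameter(iso, ref), 0, tolerance = 0.01)

  # axes are headless: adding the mirror image changes nothing
  some <- matrix(rnorm(60), ncol = 3)
  expect_equal(p2_order_parameter(rbind(some, -some), ref),
               p2_order_parameter(some, ref))
})

test_that("geometry statistics are invariant under rigid motion", {
  cs <- make_chain_config("fibril", 4, 10, seed = 2)
  R <- random_rotation(8)
  rot <- rotate_chain_set(cs, R, shift = c(10, 20, -5))
  a1 <- assign_strands(cs); a2 <- assign_strands(rot)
  expect_identical(a1$labels, a2$labels)
  al1 <- strand_axis_alignment(cs, a1); al2 <- strand_axis_alignment(rot, a2)
  expect_equal(al1$p2, al2$p2, tolerance = 1e-9)
  expect_equal(contact_number(cs)$mean, contact_number(rot)$mean)
})

test_that("PDB and XYZ round trips preserve chains to write precision", {
  cs <- make_chain_config("fibril", 3, 8, seed = 4)
  pdb <- tempfile(fileext = ".pdb")
  write_chains_pdb(cs, pdb)
  back <- read_chains_pdb(pdb)
  expect_equal(names(back$chains), names(cs$chains))
  expect_equal(back$chains$A$ca, cs$chains$A$ca, tolerance = 1e-3)

  reps <- lapply(1:3, function(s) make_chain_config("aggregate", 2, 6, seed = s))
  write_chains_pdb(reps, pdb)
  back_reps <- read_chains_pdb(pdb)
  expect_equal(length(back_reps), 3)
  expect_equal(back_reps[[2]]$chains$B$ca, reps[[2]]$chains$B$ca,
               tolerance = 1e-3)

  xyz <- tempfile(fileext = ".xyz")
  write_chains_xyz(cs, xyz)
  back2 <- read_chains_xyz(xyz)
  expect_equal(back2$chains$A$ca, cs$chains$A$ca, tolerance = 1e-3)
})
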