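# Oracle: exact tetramer-class probabilities by sampling four subunits
# without replacement (hypergeometric enumeration).
hyper_oracle <- function(n1, n2, n1_phos) {
  n <- n1 + n2
  p_hom1_all <- choose(n1, 4) / choose(n, 4)
  p_hom1_nonphos <- choose(n1 - n1_phos, 4) / choose(n, 4)
  p_hom2 <- choose(n2, 4) / choose(n, 4)
  c(p_hom1_nonphos = p_hom1_nonphos,
    p_hom1_phos = p_hom1_all - p_hom1_nonphos,
    p_hom2 = p_hom2,
    p_het = 1 - p_hom1_all - p_hom2)
}

test_that("random-rule probabilities match hand values and normalise", {
  expect_equal(
    tetramer_probabilities_random(membrane_receptor_state(0, 10, 0)),
    c(p_hom1_nonphos = 0, p_hom1_phos = 0, p_hom2 = 1, p_het = 0))
  expect_equal(
    unname(tetramer_probabilities_random(membrane_receptor_state(7, 7, 0))),
    c(1 / 16, 0, 1 / 16, 7 / 8))
  p <- tetramer_probabilities_random(membrane_receptor_state(30, 70, 10))
  expect_equal(unname(p), c(0.0016, 0.0065, 0.2401, 0.7518), tolerance = 1e-10)
  for (case in list(c(3, 9, 1), c(12.5, 0.4, 3.1), c(0.2, 0.3, 0.1))) {
    p <- tetramer_probabilities_random(
      membrane_receptor_state(case[1], case[2], case[3]))
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
  # empty membrane: all-zero without division
  expect_equal(sum(tetramer_probabilities_random(
    membrane_receptor_state(0, 0, 0))), 0)
})

test_that("the power form converges to the exact hypergeometric draw", {
  err_at <- function(scale) {
    st <- membrane_receptor_state(5 * scale, 5 * scale, scale)
    max(abs(tetramer_probabilities_random(st) -
              hyper_oracle(5 * scale, 5 * scale, scale)))
  }
  errs <- vapply(c(4, 10, 100, 1e3, 1e6), err_at, numeric(1))
  expect_lt(errs[2], 0.05)    # n = 100 subunits
  expect_lt(errs[4], 1e-3)    # n = 1e4
  expect_lt(errs[5], 1e-6)    # n = 1e7
  expect_true(all(diff(errs) < 0))
})

test_that("the dimer-of-like-dimers rule forbids 1:3 compositions", {
  # q = 1: all GluR1 homomers
  p <- tetramer_probabilities_dimer(membrane_receptor_state(12, 0, 0))
  expect_equal(unname(p["p_hom1_nonphos"]), 1)
  # the rebalanced 35:65 subunit setting: a valid distribution
  p <- tetramer_probabilities_dimer(membrane_receptor_state(35, 65, 5))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p >= 0))
  # structural check across q: heteromers arise only from unlike-dimer
  # pairs, so hom + het always exhausts the mass (no 1:3/3:1 class exists)
  for (q in c(0.1, 0.35, 0.5, 0.8)) {
    n <- 100
    p <- tetramer_probabilities_dimer(membrane_receptor_state(q * n,
                                                              (1 - q) * n, 0))
    d11 <- q^2; d12 <- 2 * q * (1 - q); d22 <- (1 - q)^2
    tot <- d11^2 + d12^2 + d22^2
    expect_equal(unname(p["p_het"]), d12^2 / tot, tolerance = 1e-12)
  }
})

test_that("gsyn weighs tetramer counts by single-channel conductances", {
  expect_equal(gsyn(membrane_receptor_state(0, 0, 0)), 0)
  expect_equal(gsyn(membrane_receptor_state(4, 0, 0)), 12.4)
  expect_equal(gsyn(membrane_receptor_state(4, 0, 4)), 18.9)
  expect_equal(gsyn(membrane_receptor_state(0, 8, 0)), 2 * 2.2)
  # monotone in the phosphorylated share at fixed pools
  g <- vapply(seq(0, 20, by = 2), function(np)
    gsyn(membrane_receptor_state(20, 30, np)), numeric(1))
  expect_true(all(diff(g) > 0))
  # floored tetramer count never exceeds the real-valued one
  expect_lte(gsyn(membrane_receptor_state(5, 4, 0), floor_count = TRUE),
             gsyn(membrane_receptor_state(5, 4, 0)))
})

test_that("homomeric-GluR1 leverage: gsyn is maximal at high GluR1 share", {
  tot <- 60
  q <- seq(0.05, 1, by = 0.05)
  g <- vapply(q, function(x)
    gsyn(membrane_receptor_state(x * tot, (1 - x) * tot, 0)), numeric(1))
  expect_equal(q[which.max(g)], 1)
  # low-GluR2 synapses start with many GluR1 homomers: the hom1 probability
  # rises steeply once GluR2 is scarce
  p_low <- tetramer_probabilities_random(membrane_receptor_state(55, 5, 0))
  p_bal <- tetramer_probabilities_random(membrane_receptor_state(30, 30, 0))
  expect_gt(p_low[["p_hom1_nonphos"]], 10 * p_bal[["p_hom1_nonphos"]])
})

test_that("unit bridges between concentrations, counts and fluxes are exact", {
  expect_equal(particles_to_concentration_rate(1, 0.5), 3.3211, tolerance = 1e-4)
  expect_equal(particles_to_concentration_rate(0, 0.5), 0)
  expect_equal(particles_to_concentration_rate(1900, 0.5) / 1000,
               6.31, tolerance = 1e-3)   # uM/ms
  expect_equal(concentration_to_subunit_count(1, 0.5), 0.30111,
               tolerance = 1e-4)
  expect_equal(concentration_to_subunit_count(0, 0.5), 0)
  expect_equal(concentration_to_subunit_count(270, 0.5), 81.3,
               tolerance = 1e-3)
  # round trip
  expect_equal(particles_to_concentration_rate(
    concentration_to_subunit_count(123, 0.5), 0.5), 123)
})

test_that("gsyn_table covers the requested grid", {
  tab <- gsyn_table(n1 = c(0, 10), n2 = c(0, 10), n1_phos = c(0, 5))
  expect_true(all(tab$n1_phos <= tab$n1))
  expect_equal(tab$gsyn[tab$n1 == 0 & tab$n2 == 0], 0)
  expect_true(all(tab$gsyn >= 0))
})
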