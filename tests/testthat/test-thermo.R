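test_that("stage free energy is the exact linear extrapolation", {
  expect_identical(stage_free_energy(4.4, 3.2, 0), 4.4)
  expect_equal(stage_free_energy(4.4, 3.2, 4.4 / 3.2), 0)
  expect_identical(stage_free_energy(0, 1.0, 2.0), -2.0)
  expect_equal(stage_free_energy(4.4, 3.2, c(0, 1, 2)), 4.4 - 3.2 * c(0, 1, 2))
  expect_error(stage_free_energy(4.4, 3.2, -0.1), "urea")
})

test_that("free energies convert to equilibrium constants via exp(-dG/RT)", {
  expect_identical(equilibrium_constant(0), 1)
  # independent arithmetic: ln K = -dG / (R T)
  expect_equal(equilibrium_constant(1.3643, 298.15),
               exp(-1.3643 / (1.9872e-3 * 298.15)))
  expect_equal(equilibrium_constant(1.3643, 298.15), 0.100, tolerance = 1e-3)
  expect_equal(equilibrium_constant(11.5, 298.15), 3.7e-9, tolerance = 0.01)
  expect_error(equilibrium_constant(1, temperature = -5), "temperature")
})

test_that("thermo_params validates its stages", {
  expect_error(thermo_params(c(1, 2), 1.5), "length")
  expect_error(thermo_params(4.4, -1), "m-values")
  expect_error(thermo_params(Inf, 1), "finite")
})

test_that("species solver hits the extreme-K limits", {
  m3 <- get_mechanism("three_state")
  native <- solve_species(m3, K = c(1e-12, 1e-12), total_protomer = 4e-6)
  expect_equal(unname(native$protomer_fractions["N2"]), 1, tolerance = 1e-8)
  unfolded <- solve_species(m3, K = c(1e12, 1e12), total_protomer = 4e-6)
  expect_equal(unname(unfolded$protomer_fractions["U"]), 1, tolerance = 1e-8)
})

test_that("species solver agrees with the dense-scan oracle", {
  m3 <- get_mechanism("three_state")
  K <- c(1, 1e-6)
  got <- solve_species(m3, K, 4e-6)$protomer_fractions
  expect_equal(got, oracle_fractions(m3, K, 4e-6), tolerance = 1e-6)

  set.seed(101)
  reg <- mechanism_registry()
  for (i in 1:1000) {
    mech <- reg[[sample(length(reg), 1L)]]
    K <- 10^stats::runif(n_transitions(mech), -12, 12)
    Pt <- 10^stats::runif(1, -8, -4)
    got <- solve_species(mech, K, Pt)$protomer_fractions
    want <- oracle_fractions(mech, K, Pt)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("protomer fractions and concentrations are conserved", {
  set.seed(202)
  reg <- mechanism_registry()
  for (i in 1:200) {
    mech <- reg[[sample(length(reg), 1L)]]
    K <- 10^stats::runif(n_transitions(mech), -12, 12)
    Pt <- 10^stats::runif(1, -8, -4)
    sp <- solve_species(mech, K, Pt)
    expect_lt(abs(sum(sp$protomer_fractions) - 1), 1e-10)
    expect_true(all(sp$protomer_fractions >= 0 &
                      sp$protomer_fractions <= 1 + 1e-12))
    total <- sum(mech$species$order * sp$concentrations)
    expect_lt(abs(total - Pt) / Pt, 1e-12)
    # mass-action relations hold
    d <- which(mech$transitions$type == "dissociation")
    conc <- sp$concentrations
    for (t in seq_len(n_transitions(mech))) {
      lhs <- if (t == d) conc[t + 1L]^2 / conc[t] else conc[t + 1L] / conc[t]
      expect_equal(unname(log(lhs)), log(K[t]), tolerance = 1e-8)
    }
  }
})

test_that("log-space fallback solver matches the closed form", {
  reg <- mechanism_registry()
  set.seed(303)
  for (i in 1:50) {
    mech <- reg[[sample(length(reg), 1L)]]
    K <- 10^stats::runif(n_transitions(mech), -12, 12)
    Pt <- 10^stats::runif(1, -8, -4)
    lc <- dimerfold:::.log_coefficients(mech, log(K))
    orders <- mech$species$order
    quad <- dimerfold:::.solve_log_monomer(lc, orders, Pt)
    root <- dimerfold:::.solve_species_log(lc[1L, ], orders, Pt)
    expect_equal(quad, root, tolerance = 1e-9)
  }
})

test_that("species solver rejects invalid inputs", {
  m3 <- get_mechanism("three_state")
  expect_error(solve_species(m3, c(1, -1), 1e-6), "equilibrium constants")
  expect_error(solve_species(m3, c(1, Inf), 1e-6), "equilibrium constants")
  expect_error(solve_species(m3, c(1, 1), 0), "total_protomer")
  expect_error(population_profile(m3, thermo_params(c(4, 11), c(3, 1)),
                                  4e-6, numeric(0)), "non-empty")
  expect_error(population_profile(m3, thermo_params(c(4, 11), c(3, 1)),
                                  4e-6, c(-1, 0)), ">= 0")
})

test_that("three-state collapses to the analytic two-state dimer limit", {
  m3 <- get_mechanism("three_state")
  dG_tot <- 15.9
  urea <- seq(0, 9, by = 0.5)
  for (dG1 in c(20, 30, 38)) {
    params <- thermo_params(c(dG1, dG_tot - dG1), c(1e-6, 4.1),
                            temperature = 298.15)
    # m1 ~ 0 keeps the first step pinned native at all urea
    pr <- population_profile(m3, params, 4e-6, urea)
    K_eff <- equilibrium_constant(stage_free_energy(dG_tot, 4.1 + 1e-6, urea))
    for (j in seq_along(urea)) {
      want <- two_state_dimer_fractions(K_eff[j], 4e-6)
      expect_equal(unname(pr$protomer_fractions[j, "N2"]),
                   unname(want["N2"]), tolerance = 1e-8)
      expect_equal(unname(pr$protomer_fractions[j, "U"]),
                   unname(want["U"]), tolerance = 1e-8)
    }
  }
})

test_that("raising any stage free energy depresses downstream species", {
  m4 <- get_mechanism("four_state")
  base <- thermo_params(c(3.8, 0.9, 12.5), c(2.8, 2.3, 0.92))
  urea <- seq(0, 9, by = 0.5)
  pr0 <- population_profile(m4, base, 2e-6, urea)$protomer_fractions
  for (s in 1:3) {
    dG <- base$dG0
    dG[s] <- dG[s] + 1.5
    pr1 <- population_profile(m4, thermo_params(dG, base$m), 2e-6,
                              urea)$protomer_fractions
    downstream <- seq(s + 1L, 4L)
    expect_true(all(pr1[, downstream] <= pr0[, downstream] + 1e-12))
  }
})

test_that("isomerization midpoints ignore protein concentration", {
  tr <- drpcp3b_truth(7)
  mids <- vapply(c(0.5, 1, 2, 4, 8) * 1e-6, function(pt) {
    transition_midpoints(tr$mechanism, tr$params, pt)$midpoint_M[1L]
  }, 0)
  expect_lt(diff(range(mids)), 1e-9)
  expect_equal(mids[[1L]], 4.4 / 3.2)
})

test_that("dissociation midpoints rise strictly with protein concentration", {
  tr <- drpcp3b_truth(7)
  pts <- c(0.5, 1, 2, 4, 8) * 1e-6
  mids <- vapply(pts, function(pt) {
    transition_midpoints(tr$mechanism, tr$params, pt)$midpoint_M[2L]
  }, 0)
  expect_true(all(diff(mids) > 0))
  # closed form at the midpoint: K_diss = Pt, so urea = (dG3 + RT ln Pt) / m3
  rt <- 1.9872e-3 * 298.15
  expect_equal(mids[[4L]], (11.5 + rt * log(4e-6)) / 0.87, tolerance = 1e-3)
})

test_that("midpoint edge cases behave", {
  m3 <- get_mechanism("three_state")
  p0 <- thermo_params(c(0, 11.5), c(3.2, 0.87))
  mids <- transition_midpoints(m3, p0, 4e-6)
  expect_equal(mids$midpoint_M[1L], 0)
  # a hugely stable dissociation never crosses 0.5 below the search bound
  p_hi <- thermo_params(c(4.4, 39), c(3.2, 0.87))
  mids_hi <- transition_midpoints(m3, p_hi, 4e-6)
  expect_false(mids_hi$in_range[2L])
  expect_true(is.na(mids_hi$midpoint_M[2L]))
})

test_that("population profiles are continuous and conserve protomers", {
  tr <- drpcp3b_truth(6)
  pr <- population_profile(tr$mechanism, tr$params, 1e-6, seq(0, 9, 0.02))
  expect_lt(max(abs(rowSums(pr$protomer_fractions) - 1)), 1e-10)
  jumps <- apply(abs(diff(pr$protomer_fractions)), 2L, max)
  expect_lt(max(jumps), 0.05)
})

test_that("the unfolded midpoint shifts right at higher protein concentration", {
  tr <- drpcp3b_truth(7)
  cross <- function(pt) {
    f <- function(u) {
      population_profile(tr$mechanism, tr$params, pt,
                         u)$protomer_fractions[1L, "U"] - 0.5
    }
    stats::uniroot(f, c(0, 12), tol = 1e-9)$root
  }
  expect_gt(cross(4e-6), cross(0.5e-6))
})

test_that("the dimeric intermediate dominates the mid-urea window at pH 7", {
  tr <- drpcp3b_truth(7)
  urea <- seq(3, 4.5, by = 0.25)
  fr <- population_profile(tr$mechanism, tr$params, 4e-6,
                           urea)$protomer_fractions
  expect_true(all(fr[, "I2"] > fr[, "N2"] & fr[, "I2"] > fr[, "U"]))
  expect_true(all(fr[, "I2"] > 0.5))
})

test_that("total free energy and m-value are sums over stages", {
  p <- thermo_params(c(4.4, 11.5), c(3.2, 0.87))
  tot <- total_free_energy(p)
  expect_equal(unname(tot["dG_total"]), 15.9)
  p6 <- drpcp3b_truth(6)$params
  expect_equal(unname(total_free_energy(p6)["dG_total"]), 17.2)
  single <- thermo_params(7.3, 1.1)
  expect_equal(unname(total_free_energy(single)["dG_total"]), 7.3)
  expect_equal(unname(total_free_energy(single)["m_total"]), 1.1)
})

test_that("mechanism validation enforces the single-dissociation chain", {
  expect_error(
    mechanism("bad",
              species = data.frame(name = c("N2", "U"), order = c(2, 1)),
              transitions = data.frame(from = "N2", to = "U",
                                       type = "isomerization")),
    "exactly one dissociation"
  )
  expect_error(
    mechanism("bad",
              species = data.frame(name = c("N2", "N2"), order = c(2, 1)),
              transitions = data.frame(from = "N2", to = "N2",
                                       type = "dissociation")),
    "unique"
  )
  expect_error(
    mechanism("bad",
              species = data.frame(name = c("N 2", "U"), order = c(2, 1)),
              transitions = data.frame(from = "N 2", to = "U",
                                       type = "dissociation")),
    "restricted"
  )
  reg <- mechanism_registry()
  expect_named(reg, c("three_state", "four_state", "monomer_intermediate"))
  expect_error(get_mechanism("five_state"), "unknown mechanism")
})
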