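# shared noiseless pH-7 fixture: generated once, reused across blocks
ph7_data <- local({
  tr <- drpcp3b_truth(7)
  ds <- generate_unfolding_datasets(
    generator_design(tr$mechanism, tr$params, ph = 7)
  )
  list(truth = tr, datasets = ds)
})

ph7_fit <- NULL
get_ph7_fit <- function() {
  if (is.null(ph7_fit)) {
    ph7_fit <<- global_fit(fit_spec(ph7_data$truth$mechanism,
                                    ph7_data$datasets))
  }
  ph7_fit
}

noisy_design <- function(seed, noise_scale = 1) {
  tr <- drpcp3b_truth(7)
  # 2% of each probe's signal range
  generator_design(tr$mechanism, tr$params, ph = 7,
                   noise_sd = noise_scale *
                     c(AEW280 = 0.18, AEW295 = 0.2, CD = 0.2),
                   seed = seed)
}

test_that("noiseless three-state data return the generating parameters", {
  fit <- get_ph7_fit()
  truth <- ph7_data$truth$params
  expect_true(fit$converged)
  expect_equal(fit$estimates$dG0, truth$dG0, tolerance = 1e-3)
  expect_equal(fit$estimates$m, truth$m, tolerance = 1e-3)
  # noiseless data: standard errors collapse to zero
  se <- standard_errors(fit)
  expect_lt(max(se / abs(c(truth$dG0, truth$m))), 1e-6)
})

test_that("noiseless four-state data return the generating parameters", {
  tr <- drpcp3b_truth(6)
  ds <- generate_unfolding_datasets(
    generator_design(tr$mechanism, tr$params, ph = 6)
  )
  fit <- global_fit(fit_spec(tr$mechanism, ds))
  expect_true(fit$converged)
  expect_equal(fit$estimates$dG0, tr$params$dG0, tolerance = 1e-3)
  expect_equal(fit$estimates$m, tr$params$m, tolerance = 1e-3)
})

test_that("the fit is invariant to dataset order and per-dataset affine scaling", {
  fit <- get_ph7_fit()
  ds <- ph7_data$datasets
  rev_fit <- global_fit(fit_spec(ph7_data$truth$mechanism, rev(ds)))
  expect_equal(rev_fit$estimates$dG0, fit$estimates$dG0, tolerance = 1e-6)
  expect_equal(rev_fit$estimates$m, fit$estimates$m, tolerance = 1e-6)

  scaled <- ds
  d3 <- scaled[[3L]]
  scaled[[3L]] <- unfolding_dataset(d3$urea, 2 * d3$signal + 5, d3$probe,
                                    d3$ph, d3$conc_uM)
  sc_fit <- global_fit(fit_spec(ph7_data$truth$mechanism, scaled))
  expect_equal(sc_fit$estimates$dG0, fit$estimates$dG0, tolerance = 1e-6)
  expect_equal(sc_fit$estimates$m, fit$estimates$m, tolerance = 1e-6)
})

test_that("degenerate single-species data trigger the identifiability warning", {
  two_state <- mechanism(
    "two_state",
    species = data.frame(name = c("N2", "U"), order = c(2, 1)),
    transitions = data.frame(from = "N2", to = "U", type = "dissociation")
  )
  u <- seq(0, 9, by = 0.5)
  flat <- unfolding_dataset(u, rep(338, length(u)), "AEW280", 7, 4)
  expect_warning(spec <- fit_spec(two_state, list(flat)), "one protein")
  expect_warning(global_fit(spec), "rank-deficient|unconstrained")
})

test_that("standard errors scale with noise and with information", {
  # the linear scaling law holds asymptotically, so probe it at low noise
  # (0.5% and 1% of the signal range)
  fit1 <- global_fit(fit_spec(drpcp3b_truth(7)$mechanism,
                              generate_unfolding_datasets(noisy_design(71,
                                                                       0.25))))
  fit2 <- global_fit(fit_spec(drpcp3b_truth(7)$mechanism,
                              generate_unfolding_datasets(noisy_design(71,
                                                                       0.5))))
  ratio <- standard_errors(fit2) / standard_errors(fit1)
  expect_true(all(ratio > 1.7 & ratio < 2.3))

  # duplicating every dataset doubles the information: SE shrinks by sqrt(2)
  ds <- generate_unfolding_datasets(noisy_design(72))
  f_single <- global_fit(fit_spec(drpcp3b_truth(7)$mechanism, ds))
  f_double <- global_fit(fit_spec(drpcp3b_truth(7)$mechanism, c(ds, ds)))
  ratio2 <- standard_errors(f_double) / standard_errors(f_single)
  expect_equal(unname(ratio2), rep(1 / sqrt(2), 4L), tolerance = 0.05)
})

test_that("noisy-replicate estimates are unbiased within Monte-Carlo error", {
  tr <- drpcp3b_truth(7)
  n_rep <- 20L
  est <- matrix(NA_real_, n_rep, 2L)
  opts <- fit_options(n_starts = 4L)
  for (r in seq_len(n_rep)) {
    ds <- generate_unfolding_datasets(noisy_design(1000 + r))
    fit <- global_fit(fit_spec(tr$mechanism, ds, options = opts))
    est[r, ] <- c(fit$estimates$dG0[1L], fit$estimates$m[1L])
  }
  mc_se <- apply(est, 2L, stats::sd) / sqrt(n_rep)
  bias <- colMeans(est) - c(tr$params$dG0[1L], tr$params$m[1L])
  expect_lt(abs(bias[1L]), 3 * mc_se[1L])
  expect_lt(abs(bias[2L]), 3 * mc_se[2L])
})

test_that("refolding datasets are accepted and flagged", {
  tr <- drpcp3b_truth(7)
  ds_u <- generate_unfolding_datasets(
    generator_design(tr$mechanism, tr$params, ph = 7)
  )
  ds_r <- generate_unfolding_datasets(
    generator_design(tr$mechanism, tr$params, ph = 7, direction = "refolding")
  )
  # reversibility: identical noiseless means regardless of direction
  expect_equal(ds_u[[1L]]$signal, ds_r[[1L]]$signal)
  fit <- global_fit(fit_spec(tr$mechanism, c(ds_u[1:4], ds_r[1:4])))
  expect_identical(fit$n_refolding, 4L)
  expect_equal(fit$estimates$dG0, tr$params$dG0, tolerance = 1e-3)
})

test_that("fit_spec validates pH consistency and init shape", {
  tr <- drpcp3b_truth(7)
  ds <- generate_unfolding_datasets(
    generator_design(tr$mechanism, tr$params, ph = 7)
  )
  d_off <- ds[[1L]]
  ds_bad <- c(ds[1:3], list(unfolding_dataset(d_off$urea, d_off$signal,
                                              "AEW280", 8, 4)))
  expect_error(fit_spec(tr$mechanism, ds_bad), "share one pH")
  expect_error(fit_spec(tr$mechanism, ds, init = thermo_params(1, 1)),
               "stages")
  expect_error(standard_errors(structure(list(converged = FALSE),
                                         class = "fit_result")), "converged")
})
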