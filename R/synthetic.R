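#' Reference stability table for zebrafish procaspase-3b
#'
#' The per-pH zero-urea free energies and m-values of DrPCP3b unfolding
#' (global-fit estimates), used as ground truth by the synthetic-data
#' generator.  Empty cells are `NA`: at pH 5 and 5.5 the native dimer is
#' already replaced by the first dimeric intermediate, so the chain starts at
#' I2 (stages 2 and 3 only); at pH 7-8.5 the second dimeric intermediate is
#' not resolved (stages 1 and 3 only); pH 6 and 6.5 resolve all three stages.
#'
#' @return data.frame with columns `ph`, `model` (registry mechanism name or
#'   `"three_state_I2"` for the low-pH chain), `dG1`, `m1`, `dG2`, `m2`,
#'   `dG3`, `m3` (kcal mol^-1 and kcal mol^-1 M^-1).
#' @export
drpcp3b_stability_table <- function() {
  data.frame(
    ph    = c(5,    5.5,  6,    6.5,  7,    7.5,  8,    8.5),
    model = c("three_state_I2", "three_state_I2", "four_state", "four_state",
              "three_state", "three_state", "three_state", "three_state"),
    dG1   = c(NA,   NA,   3.8,  5.3,  4.4,  5.4,  4.5,  2.6),
    m1    = c(NA,   NA,   2.8,  2.9,  3.2,  3.4,  2.8,  2.6),
    dG2   = c(0.5,  2.3,  0.9,  0.3,  NA,   NA,   NA,   NA),
    m2    = c(1.4,  2.6,  2.3,  1.8,  NA,   NA,   NA,   NA),
    dG3   = c(14.4, 13.1, 12.5, 11.8, 11.5, 12.6, 12.5, 11.3),
    m3    = c(1.4,  1.1,  0.92, 1.37, 0.87, 1.0,  0.9,  0.7)
  )
}

# low-pH chain: the "native" ensemble is the dimeric intermediate
.three_state_I2_mechanism <- function() {
  mechanism(
    "three_state_I2",
    species = data.frame(name = c("I2", "I2p", "U"), order = c(2L, 2L, 1L)),
    transitions = data.frame(
      from = c("I2", "I2p"), to = c("I2p", "U"),
      type = c("isomerization", "dissociation")
    )
  )
}

#' Mechanism and truth parameters for one pH of the reference table
#'
#' @param ph one of the pH values in [drpcp3b_stability_table()].
#' @return list with `mechanism`, `params` ([thermo_params()]) and `ph`.
#' @export
drpcp3b_truth <- function(ph) {
  tab <- drpcp3b_stability_table()
  row <- tab[tab$ph == ph, ]
  if (nrow(row) != 1L) {
    stop("no reference row for pH ", ph, call. = FALSE)
  }
  mech <- if (row$model == "three_state_I2") {
    .three_state_I2_mechanism()
  } else {
    get_mechanism(row$model)
  }
  dG0 <- c(row$dG1, row$dG2, row$dG3)
  m <- c(row$m1, row$m2, row$m3)
  keep <- !is.na(dG0)
  list(mechanism = mech, params = thermo_params(dG0[keep], m[keep]), ph = ph)
}

#' Species emission-peak model for spectrum synthesis
#'
#' Gaussian emission peaks (one per species) on a shared wavelength grid;
#' a mixture weighted by protomer fractions emulates the spectrum of an
#' equilibrium ensemble.  Peak positions for the native and unfolded states
#' follow the measured scans (native 338/342 nm, unfolded 347/352 nm for
#' 280/295 nm excitation); intermediate peaks are synthetic placements
#' (midway, with elevated amplitude to mimic the less-quenched
#' intermediate) and are not physiological measurements.
#'
#' @param species character vector of species names.
#' @param center peak centers, nm (within 320-380).
#' @param fwhm full width at half maximum, nm (> 0).
#' @param amplitude peak amplitudes (arbitrary units).
#' @param grid wavelength grid, nm.
#' @return object of class `spectral_model`.
#' @export
spectral_model <- function(species, center, fwhm, amplitude,
                           grid = seq(300, 400, by = 1)) {
  stopifnot(length(species) == length(center))
  fwhm <- rep_len(fwhm, length(species))
  amplitude <- rep_len(amplitude, length(species))
  if (any(center < 320) || any(center > 380)) {
    stop("peak centers must lie within [320, 380] nm", call. = FALSE)
  }
  if (any(fwhm <= 0) || any(amplitude <= 0)) {
    stop("peak widths and amplitudes must be > 0", call. = FALSE)
  }
  structure(
    list(table = data.frame(species = species, center = center, fwhm = fwhm,
                            amplitude = amplitude),
         grid = grid),
    class = "spectral_model"
  )
}

#' @rdname spectral_model
#' @param mech a [mechanism()]; peaks are assigned by species name with
#'   unmatched (intermediate) species placed midway between the native and
#'   unfolded peaks.
#' @param channel excitation channel, `"ex280"` or `"ex295"`.
#' @export
default_spectral_model <- function(mech, channel = c("ex280", "ex295")) {
  channel <- match.arg(channel)
  nat <- if (channel == "ex280") 338 else 342
  unf <- if (channel == "ex280") 347 else 352
  sp <- mech$species$name
  ns <- length(sp)
  center <- numeric(ns)
  amp <- numeric(ns)
  center[1L] <- nat; amp[1L] <- 1
  center[ns] <- unf; amp[ns] <- 1
  if (ns > 2L) {
    mid <- seq_len(ns)[-c(1L, ns)]
    # intermediates: midway peaks, elevated amplitude (less quenched)
    center[mid] <- (nat + unf) / 2
    amp[mid] <- seq(1.3, 1.15, length.out = length(mid))
  }
  spectral_model(sp, center, fwhm = 25, amplitude = amp)
}

#' Synthesize an emission spectrum from species populations
#'
#' Builds the protomer-fraction-weighted Gaussian-peak mixture and adds iid
#' Gaussian noise (clipped at zero intensity).  Warns when any populated
#' peak extends beyond the wavelength grid (the AEW of a truncated peak is
#' biased toward the grid interior).
#'
#' @param spectral a [spectral_model()].
#' @param populations a [solve_species()] result or named protomer-fraction
#'   vector.
#' @param noise_sd Gaussian noise sd, intensity units.
#' @param seed optional integer seed.
#' @return an [emission_spectrum()].
#' @export
generate_emission_spectra <- function(spectral, populations, noise_sd = 0,
                                      seed = NULL) {
  stopifnot(inherits(spectral, "spectral_model"), noise_sd >= 0)
  frac <- if (inherits(populations, "species_populations")) {
    populations$protomer_fractions
  } else {
    populations
  }
  tab <- spectral$table
  if (!all(names(frac) %in% tab$species)) {
    stop("spectral model missing species: ",
         paste(setdiff(names(frac), tab$species), collapse = ", "),
         call. = FALSE)
  }
  grid <- spectral$grid
  intensity <- numeric(length(grid))
  for (s in names(frac)) {
    if (frac[[s]] <= 0) next
    i <- match(s, tab$species)
    sd_nm <- tab$fwhm[i] / (2 * sqrt(2 * log(2)))
    if (tab$center[i] - 3 * sd_nm < min(grid) ||
        tab$center[i] + 3 * sd_nm > max(grid)) {
      warning("emission peak of species '", s,
              "' is truncated by the wavelength grid; AEW will be biased",
              call. = FALSE)
    }
    intensity <- intensity + frac[[s]] * tab$amplitude[i] *
      exp(-(grid - tab$center[i])^2 / (2 * sd_nm^2))
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    intensity <- pmax(0, intensity + stats::rnorm(length(grid), 0, noise_sd))
  }
  emission_spectrum(grid, intensity)
}

#' Default probe/concentration design
#'
#' The standard experiment at one pH: fluorescence AEW (280 and 295 nm
#' excitation) at 0.5, 1, 2 and 4 uM protomer, plus CD at 2, 4 and 8 uM —
#' eleven datasets.
#'
#' @return data.frame with columns `probe` and `conc_uM`.
#' @export
default_probe_grid <- function() {
  data.frame(
    probe = c(rep("AEW280", 4L), rep("AEW295", 4L), rep("CD", 3L)),
    conc_uM = c(0.5, 1, 2, 4, 0.5, 1, 2, 4, 2, 4, 8)
  )
}

#' Default per-probe baselines for synthesis
#'
#' Native and unfolded species carry intercept + urea slope; intermediates
#' carry intercepts only (they are populated over narrow urea windows, so
#' their slopes are not identifiable and are fixed at zero).  AEW intercepts
#' follow the measured peak positions; intermediate AEW values exceed the
#' native ones (the intermediate fluorescence is less quenched).  CD values
#' are synthetic ellipticities with no change between the two dimeric
#' intermediates (their secondary structure is indistinguishable).
#'
#' @param mech a [mechanism()].
#' @param probe `"AEW280"`, `"AEW295"` or `"CD"`.
#' @return a [baseline_set()].
#' @export
default_baselines <- function(mech, probe) {
  probe <- match.arg(probe, .PROBES)
  vals <- switch(probe,
    AEW280 = c(N2 = 338, I2 = 346, I2p = 344, I = 345.5, U = 347),
    AEW295 = c(N2 = 342, I2 = 350, I2p = 348, I = 349.5, U = 352),
    CD     = c(N2 = -12, I2 = -8.5, I2p = -8.5, I = -5, U = -2)
  )
  slopes <- switch(probe,
    AEW280 = c(first = 0.02, last = 0.05),
    AEW295 = c(first = 0.02, last = 0.05),
    CD     = c(first = 0.02, last = 0.05)
  )
  sp <- mech$species$name
  ints <- unname(vals[sp])
  if (anyNA(ints)) {
    # unknown species names: interpolate between native and unfolded anchors
    anchor <- switch(probe, AEW280 = c(338, 347), AEW295 = c(342, 352),
                     CD = c(-12, -2))
    ints[is.na(ints)] <- mean(anchor)
  }
  slp <- rep(0, length(sp))
  slp[1L] <- slopes[["first"]]
  slp[length(sp)] <- slopes[["last"]]
  baseline_set(sp, ints, slp)
}

#' Design of a synthetic unfolding experiment
#'
#' Bundles the ground truth (mechanism + thermodynamic parameters), the
#' probe/concentration grid, the urea grid, per-probe noise levels and the
#' seed.  Defaults reproduce the standard study conditions: urea 0-9 M in
#' 0.25 M steps and the eleven-dataset probe grid.
#'
#' @param mech a [mechanism()].
#' @param params a [thermo_params()] (the truth).
#' @param ph buffer pH recorded in the datasets.
#' @param probe_grid data.frame with columns `probe`, `conc_uM`.
#' @param urea urea grid, M.
#' @param noise_sd scalar or named per-probe Gaussian noise sd (signal
#'   units); 0 gives noiseless data.
#' @param seed integer seed controlling all generated noise.
#' @param direction `"unfolding"` or `"refolding"` (the equilibrium means are
#'   identical — folding is reversible; the flag is metadata).
#' @return object of class `generator_design`.
#' @export
generator_design <- function(mech, params, ph = 7,
                             probe_grid = default_probe_grid(),
                             urea = seq(0, 9, by = 0.25),
                             noise_sd = 0, seed = 1L,
                             direction = "unfolding") {
  stopifnot(inherits(mech, "mechanism"), inherits(params, "thermo_params"),
            all(c("probe", "conc_uM") %in% names(probe_grid)),
            all(noise_sd >= 0))
  direction <- match.arg(direction, c("unfolding", "refolding"))
  structure(
    list(mechanism = mech, params = params, ph = ph,
         probe_grid = as.data.frame(probe_grid), urea = urea,
         noise_sd = noise_sd, seed = as.integer(seed), direction = direction),
    class = "generator_design"
  )
}

.probe_noise <- function(noise_sd, probe) {
  if (!is.null(names(noise_sd))) {
    if (!probe %in% names(noise_sd)) {
      stop("noise_sd has names but none for probe ", probe, call. = FALSE)
    }
    noise_sd[[probe]]
  } else {
    noise_sd[[1L]]
  }
}

#' Generate synthetic unfolding datasets with known truth
#'
#' Forward model: species populations from the mass-balance solver at the
#' design truth, mapped through per-probe baselines ([predict_signal()]),
#' plus iid Gaussian noise.  The noiseless mean equals the forward model
#' exactly, so a global fit of noiseless output must return the truth.
#'
#' @param design a [generator_design()].
#' @param baselines named list of [baseline_set()] per probe; defaults to
#'   [default_baselines()] for each probe in the design.
#' @return list of [unfolding_dataset()] objects, with the truth manifest
#'   (mechanism, parameters, baselines, seed) attached as attribute
#'   `"truth"`.
#' @export
generate_unfolding_datasets <- function(design, baselines = NULL) {
  stopifnot(inherits(design, "generator_design"))
  probes <- unique(design$probe_grid$probe)
  if (is.null(baselines)) {
    baselines <- lapply(stats::setNames(probes, probes), function(p) {
      default_baselines(design$mechanism, p)
    })
  }
  if (!all(probes %in% names(baselines))) {
    stop("baselines must be a named list covering every probe in the design",
         call. = FALSE)
  }
  set.seed(design$seed)
  out <- vector("list", nrow(design$probe_grid))
  for (i in seq_len(nrow(design$probe_grid))) {
    probe <- design$probe_grid$probe[i]
    conc <- design$probe_grid$conc_uM[i]
    prof <- population_profile(design$mechanism, design$params,
                               total_protomer = conc * 1e-6,
                               urea_grid = design$urea)
    y <- predict_signal(prof, baselines[[probe]])
    sdp <- .probe_noise(design$noise_sd, probe)
    if (sdp > 0) y <- y + stats::rnorm(length(y), 0, sdp)
    wl <- if (probe == "CD") (if (design$ph < 6) 232 else 224) else NA
    out[[i]] <- unfolding_dataset(design$urea, y, probe, design$ph, conc,
                                  direction = design$direction,
                                  wavelength_nm = wl)
  }
  attr(out, "truth") <- list(mechanism = design$mechanism,
                             params = design$params,
                             baselines = baselines, seed = design$seed,
                             noise_sd = design$noise_sd)
  out
}

#' Generate a synthetic pH titration
#'
#' Single-site protonation sigmoid
#' `Y(pH) = Y_high + (Y_low - Y_high) / (1 + 10^(hill * (pH - pKa)))`
#' plus iid Gaussian noise.  At `pH = pKa` the noiseless value is the mean of
#' the two limits.
#'
#' @param pKa midpoint pH.
#' @param hill Hill coefficient (> 0); 1 for a single proton.
#' @param limits numeric `c(low, high)`: the value at low and at high pH.
#' @param ph_grid pH values.
#' @param noise_sd Gaussian noise sd, value units.
#' @param seed optional integer seed.
#' @param value_kind `"AEW"` or `"midpoint"` (metadata).
#' @return a [titration_dataset()].
#' @export
generate_titration <- function(pKa, hill = 1, limits, ph_grid,
                               noise_sd = 0, seed = NULL,
                               value_kind = "AEW") {
  stopifnot(length(limits) == 2L, hill > 0, noise_sd >= 0)
  y <- .titration_model(ph_grid, pKa, hill, limits[[1L]], limits[[2L]])
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  titration_dataset(ph_grid, y, value_kind)
}
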