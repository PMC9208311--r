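#' Fluorescence emission spectrum
#'
#' @param wavelength nm, strictly increasing (scans cover 300-400 nm).
#' @param intensity fluorescence, arbitrary units, same length; must be
#'   non-negative and not all zero.
#' @return object of class `emission_spectrum` (a data.frame with columns
#'   `wavelength_nm`, `intensity`).
#' @export
emission_spectrum <- function(wavelength, intensity) {
  stopifnot(is.numeric(wavelength), is.numeric(intensity),
            length(wavelength) == length(intensity), length(wavelength) >= 1L)
  if (any(diff(wavelength) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (any(intensity < 0) || any(!is.finite(intensity))) {
    stop("intensities must be finite and >= 0", call. = FALSE)
  }
  structure(
    data.frame(wavelength_nm = wavelength, intensity = intensity),
    class = c("emission_spectrum", "data.frame")
  )
}

#' Average emission wavelength (AEW)
#'
#' The intensity-weighted mean wavelength of an emission scan,
#' `<lambda> = sum(I_i * lambda_i) / sum(I_i)` — a robust one-number summary
#' of a spectral shift (red shift on unfolding raises it).
#'
#' @param spectrum an [emission_spectrum()], or any data.frame with columns
#'   `wavelength_nm` and `intensity`.
#' @return AEW in nm; always within `[min, max]` of the scanned wavelengths.
#' @examples
#' s <- emission_spectrum(c(300, 400), c(1, 3))
#' average_emission_wavelength(s)  # 375
#' @export
average_emission_wavelength <- function(spectrum) {
  if (!is.data.frame(spectrum) ||
      !all(c("wavelength_nm", "intensity") %in% names(spectrum))) {
    stop("spectrum must have columns `wavelength_nm` and `intensity`",
         call. = FALSE)
  }
  s <- emission_spectrum(spectrum$wavelength_nm, spectrum$intensity)
  tot <- sum(s$intensity)
  if (tot <= 0) {
    stop("average emission wavelength is undefined for an all-zero spectrum",
         call. = FALSE)
  }
  sum(s$intensity * s$wavelength_nm) / tot
}

#' Per-species spectroscopic baselines
#'
#' One intercept (signal units) and urea slope (signal units per M) per
#' mechanism species.  These are the local parameters of a global fit: the
#' signal of a pure species is `intercept + slope * urea`.
#'
#' @param species character vector of species names (must cover a mechanism).
#' @param intercept,slope numeric vectors, recycled to `length(species)`.
#' @return object of class `baseline_set` (data.frame with columns `species`,
#'   `intercept`, `slope`).
#' @export
baseline_set <- function(species, intercept, slope = 0) {
  stopifnot(is.character(species), length(species) >= 1L)
  d <- data.frame(species = species,
                  intercept = rep_len(as.numeric(intercept), length(species)),
                  slope = rep_len(as.numeric(slope), length(species)))
  if (any(!is.finite(d$intercept)) || any(!is.finite(d$slope))) {
    stop("baseline parameters must be finite", call. = FALSE)
  }
  structure(d, class = c("baseline_set", "data.frame"))
}

#' Predict the observed signal from species populations
#'
#' The observable is the protomer-fraction-weighted sum of per-species
#' linear baselines: `Y(urea) = sum_s f_s * (intercept_s + slope_s * urea)`.
#'
#' @param populations a [solve_species()] result, a [population_profile()],
#'   or a named vector of protomer fractions (or a matrix with species
#'   columns).
#' @param baselines a [baseline_set()] covering every species present.
#' @param urea urea concentration(s), M; for a `population_profile` the
#'   profile's own grid is used and `urea` must be omitted.
#' @return predicted signal, one value per urea point.
#' @export
predict_signal <- function(populations, baselines, urea = NULL) {
  stopifnot(inherits(baselines, "baseline_set"))
  if (inherits(populations, "population_profile")) {
    if (!is.null(urea)) {
      stop("urea is taken from the population_profile grid; do not supply it",
           call. = FALSE)
    }
    frac <- populations$protomer_fractions
    urea <- populations$urea
  } else if (inherits(populations, "species_populations")) {
    frac <- matrix(populations$protomer_fractions, nrow = 1L,
                   dimnames = list(NULL, names(populations$protomer_fractions)))
  } else if (is.matrix(populations)) {
    frac <- populations
  } else {
    frac <- matrix(populations, nrow = 1L,
                   dimnames = list(NULL, names(populations)))
  }
  if (is.null(urea)) urea <- 0
  species <- colnames(frac)
  if (is.null(species) || !all(species %in% baselines$species)) {
    missing_sp <- setdiff(species, baselines$species)
    stop("baselines missing for species: ",
         paste(if (length(missing_sp)) missing_sp else "(unnamed)",
               collapse = ", "), call. = FALSE)
  }
  idx <- match(species, baselines$species)
  ints <- baselines$intercept[idx]
  slps <- baselines$slope[idx]
  # Y_u = sum_s frac[u, s] * (int_s + slope_s * urea_u)
  as.numeric(frac %*% ints + (frac %*% slps) * urea)
}

.PROBES <- c("AEW280", "AEW295", "CD")

#' One equilibrium unfolding dataset
#'
#' A single probe's signal versus urea at fixed pH and total protomer
#' concentration.
#'
#' @param urea urea concentrations, M (within 0-10).
#' @param signal observed signal (nm for AEW probes, ellipticity for CD).
#' @param probe one of `"AEW280"`, `"AEW295"`, `"CD"`.
#' @param ph buffer pH (4-10).
#' @param conc_uM total protomer concentration, micromolar.
#' @param direction `"unfolding"` or `"refolding"`.
#' @param wavelength_nm monitored wavelength for CD (224 or 232), `NA`
#'   otherwise.
#' @return object of class `unfolding_dataset`.
#' @export
unfolding_dataset <- function(urea, signal, probe, ph, conc_uM,
                              direction = "unfolding", wavelength_nm = NA) {
  stopifnot(is.numeric(urea), is.numeric(signal),
            length(urea) == length(signal))
  if (length(urea) < 8L) {
    stop("an unfolding dataset needs at least 8 points", call. = FALSE)
  }
  if (any(urea < 0) || any(urea > 10)) {
    stop("urea concentrations must lie in [0, 10] M", call. = FALSE)
  }
  if (!probe %in% .PROBES) {
    stop("probe must be one of ", paste(.PROBES, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(ph) || ph < 4 || ph > 10) {
    stop("pH must lie in [4, 10]", call. = FALSE)
  }
  if (!is.numeric(conc_uM) || conc_uM <= 0) {
    stop("conc_uM must be a positive protomer concentration in uM",
         call. = FALSE)
  }
  direction <- match.arg(direction, c("unfolding", "refolding"))
  structure(
    list(urea = as.numeric(urea), signal = as.numeric(signal), probe = probe,
         ph = as.numeric(ph), conc_uM = as.numeric(conc_uM),
         direction = direction, wavelength_nm = wavelength_nm),
    class = "unfolding_dataset"
  )
}

#' @export
print.unfolding_dataset <- function(x, ...) {
  cat("<unfolding_dataset>", x$probe, "pH", x$ph, "Pt", x$conc_uM, "uM,",
      length(x$urea), "points,", x$direction, "\n")
  invisible(x)
}
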