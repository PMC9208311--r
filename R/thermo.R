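# Gas constant in kcal mol^-1 K^-1
.R_KCAL <- 1.9872e-3

.rt <- function(temperature) .R_KCAL * temperature

#' Thermodynamic parameters of a mechanism
#'
#' One (dG0, m) pair per transition of a mechanism: the zero-denaturant free
#' energy change (kcal mol^-1; 1 M protomer standard state for the
#' dissociation step) and the cooperativity index, the linear dependence of
#' the free energy on denaturant (kcal mol^-1 M^-1).
#'
#' @param dG0 numeric vector of zero-urea free energies, kcal mol^-1.
#' @param m numeric vector of m-values (must be > 0), kcal mol^-1 M^-1.
#' @param temperature kelvin; defaults to 298.15 (25 C).
#' @return object of class `thermo_params`.
#' @export
thermo_params <- function(dG0, m, temperature = 298.15) {
  stopifnot(is.numeric(dG0), is.numeric(m), length(dG0) == length(m),
            length(temperature) == 1L, temperature > 0)
  if (!all(is.finite(dG0))) stop("dG0 must be finite", call. = FALSE)
  if (!all(is.finite(m)) || any(m <= 0)) {
    stop("m-values must be finite and > 0 for unfolding transitions",
         call. = FALSE)
  }
  structure(list(dG0 = as.numeric(dG0), m = as.numeric(m),
                 temperature = as.numeric(temperature)),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("<thermo_params> T =", x$temperature, "K\n")
  print(data.frame(stage = seq_along(x$dG0),
                   dG0_kcal_mol = x$dG0, m_kcal_mol_M = x$m))
  invisible(x)
}

#' Linear-extrapolation free energy of one transition
#'
#' The free energy of each unfolding transition varies linearly with the
#' denaturant concentration: dG(urea) = dG0 - m * urea.
#'
#' @param dG0 zero-urea free energy, kcal mol^-1.
#' @param m m-value, kcal mol^-1 M^-1.
#' @param urea denaturant concentration, M (vectorized; must be >= 0).
#' @return free energy at `urea`, kcal mol^-1.
#' @examples
#' stage_free_energy(4.4, 3.2, 0)      # 4.4
#' stage_free_energy(4.4, 3.2, 1.375)  # 0 (the transition midpoint)
#' @export
stage_free_energy <- function(dG0, m, urea) {
  stopifnot(is.numeric(urea))
  if (any(urea < 0)) stop("urea concentration must be >= 0", call. = FALSE)
  dG0 - m * urea
}

#' Free energy to equilibrium constant
#'
#' K = exp(-dG / (R T)), with R = 1.9872e-3 kcal mol^-1 K^-1.  K is
#' dimensionless for isomerizations and molar for dissociation stages
#' (1 M protomer standard state).
#'
#' @param dG free energy, kcal mol^-1 (vectorized).
#' @param temperature kelvin.
#' @return equilibrium constant(s).
#' @export
equilibrium_constant <- function(dG, temperature = 298.15) {
  stopifnot(is.numeric(dG), length(temperature) == 1L)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  exp(-dG / .rt(temperature))
}

# Log-coefficients expressing every species concentration as
# exp(lc_i) * v^order_i, where v is the concentration of the first monomeric
# species (the dissociation product).  logK is a vector (one urea point) or a
# matrix (urea points x transitions).  Returns a matrix (points x species).
.log_coefficients <- function(mech, logK) {
  if (is.null(dim(logK))) logK <- matrix(logK, nrow = 1L)
  nt <- n_transitions(mech)
  ns <- nt + 1L
  stopifnot(ncol(logK) == nt)
  d <- dissociation_index(mech)
  lc <- matrix(0, nrow = nrow(logK), ncol = ns)
  # first monomer (species d + 1) is the reference: lc = 0
  if (d + 1L < ns) {
    for (j in seq.int(d + 1L, nt)) lc[, j + 1L] <- lc[, j] + logK[, j]
  }
  lc[, d] <- -logK[, d]
  if (d > 1L) {
    for (i in seq.int(d - 1L, 1L)) lc[, i] <- lc[, i + 1L] - logK[, i]
  }
  colnames(lc) <- mech$species$name
  lc
}

# Solve conservation sum(order_i * exp(lc_i + order_i * t)) = Pt for
# t = log(v) by bracketed root-finding; used when the quadratic coefficients
# are not finite in double precision.  g(t) is strictly increasing.
.solve_species_log <- function(lc, orders, total_protomer) {
  g <- function(t) {
    terms <- log(orders) + lc + orders * t
    mx <- max(terms)
    mx + log(sum(exp(terms - mx))) - log(total_protomer)
  }
  # v can never exceed Pt (monomer) and a generous lower bound comes from the
  # largest coefficient
  hi <- log(total_protomer) - min(lc, 0) + 1
  lo <- (log(total_protomer) - max(lc)) / 2 - 750
  r <- tryCatch(
    stats::uniroot(g, lower = lo, upper = hi, tol = 1e-15,
                   extendInt = "upX", maxiter = 2000L),
    error = function(e) {
      stop("species solver failed to converge: ", conditionMessage(e),
           " [Pt=", total_protomer, "]", call. = FALSE)
    }
  )
  r$root
}

# Vectorized mass-balance solve.  lc: points x species log-coefficients.
# Returns log(v) per point.
.solve_log_monomer <- function(lc, orders, total_protomer) {
  dim2 <- orders == 2L
  a <- 2 * rowSums(exp(lc[, dim2, drop = FALSE]))
  b <- rowSums(exp(lc[, !dim2, drop = FALSE]))
  ok <- is.finite(a) & is.finite(b)
  logv <- numeric(nrow(lc))
  if (any(ok)) {
    # a v^2 + b v - Pt = 0, stable branch
    disc <- sqrt(b[ok]^2 + 4 * a[ok] * total_protomer)
    logv[ok] <- log(2 * total_protomer) - log(b[ok] + disc)
  }
  if (any(!ok)) {
    for (i in which(!ok)) {
      logv[i] <- .solve_species_log(lc[i, ], orders, total_protomer)
    }
  }
  logv
}

#' Equilibrium species distribution at fixed equilibrium constants
#'
#' Solves the coupled mass-action/mass-balance system of a single-chain
#' mechanism: every consecutive pair of species obeys its equilibrium
#' constant ([X_{i+1}]/[X_i] = K_i for isomerizations,
#' [M]^2/[D] = K_d for the dissociation) and protomers are conserved,
#' 2*sum(dimers) + sum(monomers) = total.  The system reduces to a quadratic
#' in the reference monomer concentration, solved in closed form with
#' coefficients accumulated in log space; a bracketed log-space root-finder
#' handles coefficient overflow.
#'
#' @param mech a [mechanism()].
#' @param K equilibrium constants, one per transition (molar for the
#'   dissociation step).
#' @param total_protomer total protomer concentration, M.
#' @return object of class `species_populations`: list with `concentrations`
#'   (named, M), `protomer_fractions` (named, sum to 1) and `total_protomer`.
#' @examples
#' m3 <- get_mechanism("three_state")
#' solve_species(m3, K = c(1, 1e-6), total_protomer = 4e-6)
#' @export
solve_species <- function(mech, K, total_protomer) {
  stopifnot(inherits(mech, "mechanism"), is.numeric(K),
            length(K) == n_transitions(mech),
            length(total_protomer) == 1L)
  if (!is.finite(total_protomer) || total_protomer <= 0) {
    stop("total_protomer must be a finite concentration > 0", call. = FALSE)
  }
  if (any(!is.finite(K)) || any(K <= 0)) {
    stop("all equilibrium constants must be finite and > 0 (supply logs via ",
         "thermo_params/population_profile for extreme values)", call. = FALSE)
  }
  lc <- .log_coefficients(mech, log(K))
  orders <- mech$species$order
  logv <- .solve_log_monomer(lc, orders, total_protomer)
  conc <- exp(lc[1L, ] + orders * logv)
  frac <- orders * conc / total_protomer
  structure(
    list(concentrations = conc, protomer_fractions = frac,
         total_protomer = total_protomer),
    class = "species_populations"
  )
}

#' @export
print.species_populations <- function(x, ...) {
  cat("<species_populations> Pt =", format(x$total_protomer, digits = 6), "M\n")
  print(round(x$protomer_fractions, 6))
  invisible(x)
}

# fractions matrix (urea points x species) for a parameterized mechanism
.fractions_matrix <- function(mech, dG0, m, total_protomer, urea,
                              temperature = 298.15) {
  rt <- .rt(temperature)
  # logK[u, t] = -(dG0_t - m_t * urea_u) / RT
  logK <- outer(urea, m) / rt
  logK <- sweep(logK, 2L, dG0 / rt, "-")
  lc <- .log_coefficients(mech, logK)
  orders <- mech$species$order
  logv <- .solve_log_monomer(lc, orders, total_protomer)
  conc <- exp(lc + outer(logv, orders))
  frac <- sweep(conc, 2L, orders, "*") / total_protomer
  colnames(frac) <- mech$species$name
  list(fractions = frac, concentrations = conc)
}

#' Species populations over a urea grid
#'
#' Evaluates the equilibrium distribution of every species of a mechanism
#' across a denaturant grid at fixed total protomer concentration — the
#' fraction-of-species landscape.
#'
#' @param mech a [mechanism()].
#' @param params a [thermo_params()] (one stage per transition).
#' @param total_protomer total protomer concentration, M.
#' @param urea_grid non-empty vector of urea concentrations, M (>= 0).
#' @return object of class `population_profile`: list with `urea`,
#'   `protomer_fractions` (matrix, points x species), `concentrations`,
#'   `total_protomer` and the mechanism.
#' @export
population_profile <- function(mech, params, total_protomer,
                               urea_grid = seq(0, 9, by = 0.1)) {
  stopifnot(inherits(mech, "mechanism"), inherits(params, "thermo_params"),
            length(params$dG0) == n_transitions(mech))
  if (length(urea_grid) == 0L) stop("urea_grid must be non-empty", call. = FALSE)
  if (any(urea_grid < 0)) stop("urea concentrations must be >= 0", call. = FALSE)
  if (!is.finite(total_protomer) || total_protomer <= 0) {
    stop("total_protomer must be a finite concentration > 0", call. = FALSE)
  }
  fm <- .fractions_matrix(mech, params$dG0, params$m, total_protomer,
                          urea_grid, params$temperature)
  structure(
    list(urea = urea_grid, protomer_fractions = fm$fractions,
         concentrations = fm$concentrations,
         total_protomer = total_protomer, mechanism = mech, params = params),
    class = "population_profile"
  )
}

#' @export
as.data.frame.population_profile <- function(x, ...) {
  data.frame(urea_M = x$urea, x$protomer_fractions, check.names = FALSE)
}

#' Total conformational free energy
#'
#' The conformational stability of the dimer: the sum of the per-transition
#' zero-denaturant free energies, and the total m-value as the sum of the
#' stage m-values.
#'
#' @param params a [thermo_params()].
#' @return named numeric `c(dG_total, m_total)`, kcal mol^-1 and
#'   kcal mol^-1 M^-1.
#' @export
total_free_energy <- function(params) {
  stopifnot(inherits(params, "thermo_params"))
  c(dG_total = sum(params$dG0), m_total = sum(params$m))
}

#' Transition midpoints
#'
#' For isomerizations the midpoint is the closed form dG0/m (where the two
#' flanking species are equally populated regardless of protein
#' concentration).  For the dissociation step the midpoint is the urea where
#' the total monomeric protomer fraction crosses 0.5, found numerically;
#' it depends on the total protomer concentration.
#'
#' @param mech a [mechanism()].
#' @param params a [thermo_params()].
#' @param total_protomer total protomer concentration, M.
#' @param search upper urea bound for the numeric search, M.
#' @return data.frame with columns `from`, `to`, `type`, `midpoint_M` and
#'   `in_range` (FALSE when no crossing exists in `[0, search]`; the midpoint
#'   is then `NA`).
#' @export
transition_midpoints <- function(mech, params, total_protomer, search = 12) {
  stopifnot(inherits(mech, "mechanism"), inherits(params, "thermo_params"))
  d <- dissociation_index(mech)
  mono <- which(mech$species$order == 1L)
  mid <- numeric(n_transitions(mech))
  ok <- logical(n_transitions(mech))
  for (i in seq_len(n_transitions(mech))) {
    if (i == d) {
      f <- function(u) {
        fm <- .fractions_matrix(mech, params$dG0, params$m, total_protomer,
                                u, params$temperature)
        sum(fm$fractions[1L, mono]) - 0.5
      }
      lo <- f(0); hi <- f(search)
      if (lo > 0 || hi < 0) {
        mid[i] <- NA_real_; ok[i] <- FALSE
      } else {
        mid[i] <- stats::uniroot(f, c(0, search), tol = 1e-10)$root
        ok[i] <- TRUE
      }
    } else {
      mid[i] <- params$dG0[i] / params$m[i]
      ok[i] <- mid[i] >= 0 && mid[i] <= search
    }
  }
  data.frame(
    from = mech$transitions$from, to = mech$transitions$to,
    type = mech$transitions$type, midpoint_M = mid, in_range = ok
  )
}
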