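#' Optimizer and multi-start options for a global fit
#'
#' @param n_starts number of best grid candidates refined by full
#'   Levenberg-Marquardt runs (the coarse grid itself is screened
#'   exhaustively by objective value; runs stop early once a start reaches
#'   an objective indistinguishable from zero at double precision).
#' @param grid_dG,grid_m coarse multi-start grid per stage, kcal mol^-1 and
#'   kcal mol^-1 M^-1.
#' @param lower_dG,upper_dG,lower_m,upper_m parameter bounds.
#' @param ftol,ptol convergence tolerances passed to [minpack.lm::nls.lm()].
#' @param max_eval maximum residual evaluations per optimizer run.
#' @param seed integer seed recorded with the fit (governs any randomized
#'   start jitter; the default start grid is deterministic).
#' @return list of class `fit_options`.
#' @export
fit_options <- function(n_starts = 20L,
                        grid_dG = c(2, 5, 10, 15), grid_m = c(0.5, 1.5, 3),
                        lower_dG = -5, upper_dG = 40,
                        lower_m = 0.01, upper_m = 10,
                        ftol = 1e-10, ptol = 1e-10, max_eval = 10000L,
                        seed = 1L) {
  structure(
    list(n_starts = as.integer(n_starts), grid_dG = grid_dG, grid_m = grid_m,
         lower_dG = lower_dG, upper_dG = upper_dG,
         lower_m = lower_m, upper_m = upper_m,
         ftol = ftol, ptol = ptol, max_eval = as.integer(max_eval),
         seed = as.integer(seed)),
    class = "fit_options"
  )
}

#' Specification of a global fit
#'
#' All datasets at one pH, the mechanism to fit, optional starting values and
#' optimizer options.  Thermodynamic parameters (dG0 and m per transition)
#' are linked across datasets; per-species spectroscopic baselines are local
#' to each dataset.
#'
#' @param mech a [mechanism()].
#' @param datasets list of [unfolding_dataset()] objects sharing one pH.
#' @param init optional [thermo_params()] starting values (added to the
#'   multi-start set).
#' @param options a [fit_options()].
#' @return object of class `fit_spec`.
#' @export
fit_spec <- function(mech, datasets, init = NULL, options = fit_options()) {
  stopifnot(inherits(mech, "mechanism"), is.list(datasets),
            length(datasets) >= 1L)
  for (d in datasets) {
    if (!inherits(d, "unfolding_dataset")) {
      stop("datasets must be unfolding_dataset objects", call. = FALSE)
    }
  }
  phs <- vapply(datasets, `[[`, 0, "ph")
  if (length(unique(phs)) != 1L) {
    stop("all datasets of a global fit must share one pH (found: ",
         paste(sort(unique(phs)), collapse = ", "), ")", call. = FALSE)
  }
  if (!is.null(init)) {
    stopifnot(inherits(init, "thermo_params"))
    if (length(init$dG0) != n_transitions(mech)) {
      stop("init has ", length(init$dG0), " stages; mechanism has ",
           n_transitions(mech), call. = FALSE)
    }
  }
  concs <- unique(vapply(datasets, `[[`, 0, "conc_uM"))
  if (length(concs) < 2L) {
    warning("only one protein concentration supplied for a mechanism with a ",
            "dissociation step: the dissociation free energy and m-value ",
            "may not be identifiable", call. = FALSE)
  }
  structure(
    list(mechanism = mech, datasets = datasets, init = init,
         options = options, ph = phs[[1L]]),
    class = "fit_spec"
  )
}

# 1/sd weight per dataset: empirical pre-transition (urea <= 1.5 M, linearly
# detrended) standard deviation, falling back to the signal range when the
# pre-transition is noiseless or too short.
.dataset_weight <- function(d) {
  rng <- diff(range(d$signal))
  if (rng == 0) return(1)
  pre <- d$urea <= 1.5
  s <- NA_real_
  if (sum(pre) >= 4L) {
    r <- stats::lm.fit(cbind(1, d$urea[pre]), d$signal[pre])$residuals
    s <- stats::sd(r)
  }
  if (!is.finite(s) || s < 1e-6 * rng) s <- rng
  1 / s
}

# design matrix for the local (baseline) parameters of one dataset:
# an intercept column per species (the fraction itself) and a slope column
# for the native and unfolded species (fraction * urea)
.baseline_design <- function(frac, urea) {
  ns <- ncol(frac)
  slope_cols <- c(1L, ns)
  X <- cbind(frac, frac[, slope_cols, drop = FALSE] * urea)
  colnames(X) <- c(paste0("int_", colnames(frac)),
                   paste0("slope_", colnames(frac)[slope_cols]))
  X
}

.unpack_theta <- function(theta, k) {
  list(dG0 = theta[seq_len(k)], m = theta[k + seq_len(k)])
}

# variable-projection residuals: baselines solved by least squares per
# dataset given the linked thermodynamic parameters
.vp_residuals <- function(theta, ctx) {
  p <- .unpack_theta(theta, ctx$k)
  out <- vector("list", length(ctx$datasets))
  for (j in seq_along(ctx$datasets)) {
    d <- ctx$datasets[[j]]
    fr <- .fractions_matrix(ctx$mech, p$dG0, p$m, d$conc_uM * 1e-6, d$urea,
                            ctx$temperature)$fractions
    X <- .baseline_design(fr, d$urea)
    qx <- qr(X)
    out[[j]] <- ctx$w[j] * as.numeric(d$signal - qr.fitted(qx, d$signal))
  }
  ctx$n_eval <- ctx$n_eval + 1L
  unlist(out)
}

# solved baseline coefficients at fixed theta (NA for aliased columns -> 0)
.vp_baselines <- function(theta, ctx) {
  p <- .unpack_theta(theta, ctx$k)
  lapply(ctx$datasets, function(d) {
    fr <- .fractions_matrix(ctx$mech, p$dG0, p$m, d$conc_uM * 1e-6, d$urea,
                            ctx$temperature)$fractions
    X <- .baseline_design(fr, d$urea)
    beta <- qr.coef(qr(X), d$signal)
    beta[is.na(beta)] <- 0
    beta
  })
}

# residuals of the full model (linked + all local parameters free)
.full_residuals <- function(par, ctx) {
  theta <- par[seq_len(2L * ctx$k)]
  p <- .unpack_theta(theta, ctx$k)
  out <- vector("list", length(ctx$datasets))
  pos <- 2L * ctx$k
  for (j in seq_along(ctx$datasets)) {
    d <- ctx$datasets[[j]]
    nb <- ctx$nbeta[j]
    beta <- par[pos + seq_len(nb)]
    pos <- pos + nb
    fr <- .fractions_matrix(ctx$mech, p$dG0, p$m, d$conc_uM * 1e-6, d$urea,
                            ctx$temperature)$fractions
    X <- .baseline_design(fr, d$urea)
    out[[j]] <- ctx$w[j] * as.numeric(d$signal - X %*% beta)
  }
  ctx$n_eval <- ctx$n_eval + 1L
  unlist(out)
}

.theta_grid <- function(k, grid_dG, grid_m) {
  per_stage <- as.matrix(expand.grid(dG = grid_dG, m = grid_m))
  idx <- expand.grid(rep(list(seq_len(nrow(per_stage))), k))
  n <- nrow(idx)
  theta <- matrix(0, nrow = n, ncol = 2L * k)
  for (s in seq_len(k)) {
    theta[, s] <- per_stage[idx[[s]], "dG"]
    theta[, k + s] <- per_stage[idx[[s]], "m"]
  }
  theta
}

#' Global fit of equilibrium unfolding data
#'
#' Fits all datasets of a [fit_spec()] simultaneously: the per-transition
#' free energies and m-values are linked (shared by every dataset), while
#' the per-species spectroscopic baselines are local.  Each dataset's
#' residuals are weighted by its empirical pre-transition noise (fallback:
#' signal range).  The search runs in two phases: a coarse multi-start grid
#' on the linked parameters is screened with baselines profiled out by
#' weighted least squares (variable projection), the best candidates are
#' optimized by bounded Levenberg-Marquardt, and the winner is refined over
#' the full parameter set to convergence.  Standard errors come from the
#' curvature of the full model, `sqrt(diag(s^2 (J'WJ)^-1))`.
#'
#' @param spec a [fit_spec()].
#' @return object of class `fit_result`: `estimates` ([thermo_params()]),
#'   `baselines` (named-vector list per dataset), `standard_errors` and
#'   `covariance` over the linked parameters, per-dataset `residuals` and
#'   `fitted`, weighted `objective`, `converged`, `n_evaluations`,
#'   `mechanism`, `ph`, `datasets` and `weights`.
#' @export
global_fit <- function(spec) {
  stopifnot(inherits(spec, "fit_spec"))
  mech <- spec$mechanism
  k <- n_transitions(mech)
  opt <- spec$options
  ctx <- new.env(parent = emptyenv())
  ctx$mech <- mech
  ctx$k <- k
  ctx$datasets <- spec$datasets
  ctx$temperature <- if (!is.null(spec$init)) spec$init$temperature else 298.15
  ctx$w <- vapply(spec$datasets, .dataset_weight, 0)
  ctx$n_eval <- 0L
  set.seed(opt$seed)

  lower <- c(rep(opt$lower_dG, k), rep(opt$lower_m, k))
  upper <- c(rep(opt$upper_dG, k), rep(opt$upper_m, k))
  clamp <- function(th) pmin(pmax(th, lower), upper)

  # phase 1: exhaustive screen of the coarse grid
  grid <- .theta_grid(k, opt$grid_dG, opt$grid_m)
  obj <- vapply(seq_len(nrow(grid)), function(i) {
    tryCatch(sum(.vp_residuals(grid[i, ], ctx)^2),
             error = function(e) Inf)
  }, 0)
  ord <- order(obj)
  starts <- lapply(ord[seq_len(min(opt$n_starts, nrow(grid)))],
                   function(i) grid[i, ])
  if (!is.null(spec$init)) {
    starts <- c(list(clamp(c(spec$init$dG0, spec$init$m))), starts)
  }

  # phase 2: bounded LM from each retained start, baselines profiled out
  ctl <- minpack.lm::nls.lm.control(
    ftol = opt$ftol, ptol = opt$ptol, maxiter = 1000L,
    maxfev = opt$max_eval
  )
  # a weighted SSR at double-precision rounding of the data is as good as
  # zero: no later start can beat it meaningfully
  ssr_floor <- 1e-16 *
    sum(vapply(seq_along(ctx$datasets), function(j) {
      sum((ctx$w[j] * ctx$datasets[[j]]$signal)^2)
    }, 0))
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = .vp_residuals, ctx = ctx,
                         lower = lower, upper = upper, control = ctl),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
    if (best$ssr <= ssr_floor) break
  }
  if (is.null(best)) {
    stop("global fit failed: no optimizer start converged", call. = FALSE)
  }

  # phase 3: full refinement over linked + local parameters
  theta <- best$fit$par
  betas <- .vp_baselines(theta, ctx)
  ctx$nbeta <- vapply(betas, length, 0L)
  par0 <- c(theta, unlist(betas, use.names = FALSE))
  lower_f <- c(lower, rep(-Inf, sum(ctx$nbeta)))
  upper_f <- c(upper, rep(Inf, sum(ctx$nbeta)))
  ctl2 <- minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                     maxiter = 500L, maxfev = opt$max_eval)
  full <- minpack.lm::nls.lm(par = par0, fn = .full_residuals, ctx = ctx,
                             lower = lower_f, upper = upper_f, control = ctl2)
  par <- full$par
  theta <- par[seq_len(2L * k)]
  p <- .unpack_theta(theta, k)
  estimates <- thermo_params(p$dG0, p$m, ctx$temperature)

  pos <- 2L * k
  baselines <- vector("list", length(spec$datasets))
  fitted <- vector("list", length(spec$datasets))
  residuals <- vector("list", length(spec$datasets))
  for (j in seq_along(spec$datasets)) {
    d <- spec$datasets[[j]]
    nb <- ctx$nbeta[j]
    beta <- par[pos + seq_len(nb)]
    pos <- pos + nb
    fr <- .fractions_matrix(mech, p$dG0, p$m, d$conc_uM * 1e-6, d$urea,
                            ctx$temperature)$fractions
    X <- .baseline_design(fr, d$urea)
    names(beta) <- colnames(X)
    baselines[[j]] <- beta
    fitted[[j]] <- as.numeric(X %*% beta)
    residuals[[j]] <- d$signal - fitted[[j]]
  }

  npar <- length(par)
  nres <- length(full$fvec)
  ssr <- sum(full$fvec^2)
  s2 <- if (nres > npar) ssr / (nres - npar) else 0
  theta_names <- c(paste0("dG", seq_len(k)), paste0("m", seq_len(k)))
  cov_linked <- matrix(NA_real_, 2L * k, 2L * k,
                       dimnames = list(theta_names, theta_names))
  se <- stats::setNames(rep(NA_real_, 2L * k), theta_names)
  h <- full$hessian
  ev <- eigen(h, symmetric = TRUE, only.values = FALSE)
  tol_ev <- max(ev$values) * 1e-12
  if (min(ev$values) <= tol_ev) {
    flat <- which(ev$values <= tol_ev)
    load <- abs(ev$vectors[seq_len(2L * k), flat, drop = FALSE])
    culprits <- theta_names[rowSums(load) > 0.1]
    warning("information matrix is rank-deficient; unconstrained or nearly ",
            "unconstrained linked parameters: ",
            if (length(culprits)) paste(culprits, collapse = ", ")
            else "(local baseline parameters only)",
            call. = FALSE)
  } else {
    covm <- s2 * chol2inv(chol(h))
    cov_linked <- covm[seq_len(2L * k), seq_len(2L * k), drop = FALSE]
    dimnames(cov_linked) <- list(theta_names, theta_names)
    se <- stats::setNames(sqrt(pmax(0, diag(cov_linked))), theta_names)
  }

  structure(
    list(estimates = estimates, baselines = baselines,
         standard_errors = se, covariance = cov_linked,
         residuals = residuals, fitted = fitted, objective = ssr,
         converged = full$info %in% 1:4, n_evaluations = ctx$n_eval,
         mechanism = mech, ph = spec$ph, datasets = spec$datasets,
         weights = ctx$w, s2 = s2,
         n_refolding = sum(vapply(spec$datasets, `[[`, "", "direction") ==
                             "refolding"),
         seed = opt$seed),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  k <- length(x$estimates$dG0)
  cat("<fit_result>", x$mechanism$name, "at pH", x$ph, "|",
      length(x$datasets), "datasets",
      if (x$n_refolding > 0) paste0("(", x$n_refolding, " refolding)"),
      "\n  converged:", x$converged,
      " objective:", format(x$objective, digits = 6), "\n")
  tab <- data.frame(
    transition = paste(x$mechanism$transitions$from, "->",
                       x$mechanism$transitions$to),
    dG0 = x$estimates$dG0, dG0_se = x$standard_errors[seq_len(k)],
    m = x$estimates$m, m_se = x$standard_errors[k + seq_len(k)]
  )
  print(tab, digits = 4)
  tot <- total_free_energy(x$estimates)
  cat("  dG_total:", format(tot[["dG_total"]], digits = 4),
      "kcal/mol  m_total:", format(tot[["m_total"]], digits = 4),
      "kcal/mol/M\n")
  invisible(x)
}

#' Standard errors of the linked parameters
#'
#' Curvature-based errors, `sqrt(diag((J'WJ)^-1 s^2))` with `s^2` the
#' weighted residual variance of the converged fit.
#'
#' @param result a [global_fit()] result.
#' @return named numeric vector (dG and m per stage).
#' @export
standard_errors <- function(result) {
  stopifnot(inherits(result, "fit_result"))
  if (!result$converged) {
    stop("standard errors are only reported for converged fits",
         call. = FALSE)
  }
  if (anyNA(result$standard_errors)) {
    stop("information matrix was singular: standard errors unavailable ",
         "(identifiability)", call. = FALSE)
  }
  result$standard_errors
}
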