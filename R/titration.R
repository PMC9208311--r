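#' pH titration dataset
#'
#' @param ph pH values (any order; stored sorted). At least 5 points spanning
#'   at least 1.5 pH units.
#' @param value observed values (nm for AEW, M urea for transition
#'   midpoints).
#' @param value_kind `"AEW"` or `"midpoint"`.
#' @return object of class `titration_dataset`.
#' @export
titration_dataset <- function(ph, value, value_kind = c("AEW", "midpoint")) {
  value_kind <- match.arg(value_kind)
  stopifnot(is.numeric(ph), is.numeric(value), length(ph) == length(value))
  if (length(ph) < 5L) {
    stop("a titration needs at least 5 points", call. = FALSE)
  }
  if (diff(range(ph)) < 1.5) {
    stop("titration pH values must span at least 1.5 units", call. = FALSE)
  }
  o <- order(ph)
  if (anyDuplicated(ph)) {
    stop("duplicate pH values are not supported", call. = FALSE)
  }
  structure(
    list(ph = ph[o], value = value[o], value_kind = value_kind),
    class = "titration_dataset"
  )
}

# Y(pH) = Y_high + (Y_low - Y_high) / (1 + 10^(hill * (pH - pKa)))
.titration_model <- function(ph, pKa, hill, y_low, y_high) {
  f <- 1 / (1 + 10^(hill * (ph - pKa)))   # fraction in the low-pH form
  y_high + (y_low - y_high) * f
}

# weighted linear solve of the limits for fixed (pKa, hill); returns SSR and
# coefficients
.titration_linear <- function(ph, value, pKa, hill) {
  f <- 1 / (1 + 10^(hill * (ph - pKa)))
  X <- cbind(low = f, high = 1 - f)
  fit <- stats::lm.fit(X, value)
  list(ssr = sum(fit$residuals^2), coef = fit$coefficients)
}

#' Fit a single-site protonation (pKa) model
#'
#' Least-squares fit of
#' `Y(pH) = Y_high + (Y_low - Y_high) / (1 + 10^(hill * (pH - pKa)))`
#' to a titration.  The limits enter linearly and are profiled out during a
#' coarse pKa (and optionally Hill) grid screen; the best candidate is
#' polished by Levenberg-Marquardt over all parameters.  The Hill
#' coefficient is fixed at 1 (single proton) unless another value is
#' supplied or it is freed.
#'
#' @param data a [titration_dataset()].
#' @param hill fixed Hill coefficient (ignored when `free_hill = TRUE`).
#' @param free_hill estimate the Hill coefficient as a free parameter.
#' @return object of class `titration_fit`: list with `pKa`, `low_limit`,
#'   `high_limit`, `hill`, `standard_errors`, `residuals`, `fitted`,
#'   `objective`, `extrapolated` (TRUE when pKa falls outside the sampled
#'   pH range +- 1) and `converged`.
#' @export
fit_pka <- function(data, hill = 1, free_hill = FALSE) {
  stopifnot(inherits(data, "titration_dataset"), hill > 0)
  ph <- data$ph
  y <- data$value
  rng <- diff(range(y))
  # noise scale from second differences (removes the smooth trend)
  noise <- if (length(y) >= 4L) stats::sd(diff(y, differences = 2L)) / sqrt(6)
           else 0
  if (rng == 0 || rng < 3 * noise) {
    stop("no transition detected: value range (", signif(rng, 3),
         ") is below 3x the noise estimate (", signif(noise, 3), ")",
         call. = FALSE)
  }

  pka_grid <- seq(min(ph) - 1, max(ph) + 1, by = 0.05)
  hill_grid <- if (free_hill) c(0.5, 1, 2, 4) else hill
  best <- NULL
  for (h in hill_grid) {
    ssr <- vapply(pka_grid, function(p) {
      .titration_linear(ph, y, p, h)$ssr
    }, 0)
    i <- which.min(ssr)
    if (is.null(best) || ssr[i] < best$ssr) {
      best <- list(pKa = pka_grid[i], hill = h, ssr = ssr[i])
    }
  }
  lin <- .titration_linear(ph, y, best$pKa, best$hill)

  resid_fn <- function(p) {
    h <- if (free_hill) p[["hill"]] else hill
    y - .titration_model(ph, p[["pKa"]], h, p[["low"]], p[["high"]])
  }
  start <- c(pKa = best$pKa, low = unname(lin$coef[["low"]]),
             high = unname(lin$coef[["high"]]))
  lower <- c(min(ph) - 3, -Inf, -Inf)
  upper <- c(max(ph) + 3, Inf, Inf)
  if (free_hill) {
    start <- c(start, hill = best$hill)
    lower <- c(lower, 1e-3)
    upper <- c(upper, 20)
  }
  ctl <- minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                    maxiter = 1000L)
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn, lower = lower,
                            upper = upper, control = ctl)
  p <- fit$par
  est_hill <- if (free_hill) p[["hill"]] else hill
  fitted <- .titration_model(ph, p[["pKa"]], est_hill, p[["low"]], p[["high"]])
  res <- y - fitted
  npar <- length(p)
  dof <- max(1L, length(y) - npar)
  s2 <- sum(res^2) / dof
  se <- rep(NA_real_, npar)
  cov <- tryCatch(s2 * solve(fit$hessian), error = function(e) NULL)
  if (!is.null(cov)) se <- sqrt(pmax(0, diag(cov)))
  names(se) <- names(p)
  extrap <- p[["pKa"]] < min(ph) - 1 || p[["pKa"]] > max(ph) + 1
  if (extrap) {
    warning("fitted pKa (", signif(p[["pKa"]], 4),
            ") lies outside the sampled pH range; treat as extrapolated",
            call. = FALSE)
  }
  structure(
    list(pKa = unname(p[["pKa"]]), low_limit = unname(p[["low"]]),
         high_limit = unname(p[["high"]]), hill = unname(est_hill),
         hill_free = free_hill, standard_errors = se, residuals = res,
         fitted = fitted, objective = sum(res^2),
         extrapolated = extrap, converged = fit$info %in% 1:4,
         data = data),
    class = "titration_fit"
  )
}

#' @export
print.titration_fit <- function(x, ...) {
  cat("<titration_fit> pKa =", signif(x$pKa, 4),
      if (x$hill_free) paste0("(hill = ", signif(x$hill, 3), ", freed)")
      else paste0("(hill fixed at ", x$hill, ")"),
      "\n  limits:", signif(x$low_limit, 5), "(low pH) ->",
      signif(x$high_limit, 5), "(high pH)\n")
  invisible(x)
}

#' Assemble first-transition midpoints versus pH
#'
#' Collects the closed-form midpoint (dG1/m1) of the native-dimer
#' isomerization (N2 -> I2) from a collection of per-pH global fits into a
#' titration dataset ready for [fit_pka()].  pH values whose mechanism lacks
#' the N2 -> I2 stage (e.g. low-pH chains that start at I2) are skipped and
#' recorded in the `"skipped"` attribute.
#'
#' @param fits list of per-pH fit results — any objects carrying `$mechanism`,
#'   `$estimates` (a [thermo_params()]) and `$ph`.
#' @return a [titration_dataset()] with `value_kind = "midpoint"`; skipped
#'   pH values in `attr(, "skipped")`.
#' @export
midpoints_vs_ph <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  ph <- numeric(0)
  mid <- numeric(0)
  skipped <- numeric(0)
  for (f in fits) {
    if (is.null(f$mechanism) || is.null(f$estimates) || is.null(f$ph)) {
      stop("each fit must carry $mechanism, $estimates and $ph", call. = FALSE)
    }
    tr <- f$mechanism$transitions
    i <- which(tr$from == "N2" & tr$to == "I2")
    if (length(i) != 1L) {
      skipped <- c(skipped, f$ph)
      next
    }
    ph <- c(ph, f$ph)
    mid <- c(mid, f$estimates$dG0[i] / f$estimates$m[i])
  }
  if (length(ph) < 5L) {
    stop("fewer than 5 usable pH values (", length(ph), " usable, ",
         length(skipped), " skipped): cannot assemble a titration",
         call. = FALSE)
  }
  out <- titration_dataset(ph, mid, "midpoint")
  attr(out, "skipped") <- skipped
  out
}
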