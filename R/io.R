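# numbers are serialized at 17 significant digits so text round-trips are
# bit-for-bit for doubles
.fmt17 <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 17L, format = "g"))
}

#' Write / read one unfolding dataset as CSV
#'
#' Plain comma-separated text with a `# key: value` metadata header block
#' (probe, pH, protomer concentration in uM, direction, monitored
#' wavelength) followed by `urea_M,signal` columns.  Values round-trip
#' bit-for-bit.
#'
#' @param d an [unfolding_dataset()].
#' @param path file path.
#' @return `write_unfolding_csv()` returns `path` invisibly;
#'   `read_unfolding_csv()` returns an [unfolding_dataset()].
#' @export
write_unfolding_csv <- function(d, path) {
  stopifnot(inherits(d, "unfolding_dataset"))
  hdr <- c(
    paste("# probe:", d$probe),
    paste("# ph:", .fmt17(d$ph)),
    paste("# conc_uM:", .fmt17(d$conc_uM)),
    paste("# direction:", d$direction),
    paste("# wavelength_nm:", .fmt17(d$wavelength_nm))
  )
  body <- paste(.fmt17(d$urea), .fmt17(d$signal), sep = ",")
  writeLines(c(hdr, "urea_M,signal", body), path)
  invisible(path)
}

.parse_header <- function(lines, path) {
  meta <- list()
  for (ln in lines) {
    kv <- sub("^#\\s*", "", ln)
    i <- regexpr(":", kv, fixed = TRUE)
    if (i < 0) {
      stop("malformed metadata line in ", path, ": '", ln, "'", call. = FALSE)
    }
    meta[[trimws(substr(kv, 1L, i - 1L))]] <- trimws(substring(kv, i + 1L))
  }
  meta
}

#' @rdname write_unfolding_csv
#' @export
read_unfolding_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  n_meta <- if (any(!is_meta)) which(!is_meta)[1L] - 1L else length(lines)
  meta <- .parse_header(lines[seq_len(n_meta)], path)
  for (key in c("probe", "ph", "conc_uM")) {
    if (is.null(meta[[key]])) {
      stop("dataset ", path, " is missing metadata '", key, "'",
           call. = FALSE)
    }
  }
  body <- lines[-seq_len(n_meta)]
  tab <- tryCatch(
    utils::read.csv(text = body, header = TRUE),
    error = function(e) {
      stop("malformed CSV body in ", path, " (starting at line ",
           n_meta + 1L, "): ", conditionMessage(e), call. = FALSE)
    }
  )
  if (!all(c("urea_M", "signal") %in% names(tab))) {
    stop(path, ": expected columns urea_M,signal at line ", n_meta + 1L,
         call. = FALSE)
  }
  urea <- suppressWarnings(as.numeric(tab$urea_M))
  signal <- suppressWarnings(as.numeric(tab$signal))
  bad <- which(!is.finite(urea) | !is.finite(signal))
  if (length(bad)) {
    stop(path, ": non-numeric value at line ", n_meta + 1L + bad[1L],
         call. = FALSE)
  }
  unfolding_dataset(
    urea, signal, probe = meta$probe, ph = as.numeric(meta$ph),
    conc_uM = as.numeric(meta$conc_uM),
    direction = if (is.null(meta$direction)) "unfolding" else meta$direction,
    wavelength_nm = if (is.null(meta$wavelength_nm)) NA
                    else suppressWarnings(as.numeric(meta$wavelength_nm))
  )
}

#' Read an emission scan CSV
#'
#' Two columns, `wavelength_nm,intensity`.
#'
#' @param path file path.
#' @return an [emission_spectrum()].
#' @export
read_emission_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, header = TRUE)
  if (!all(c("wavelength_nm", "intensity") %in% names(tab))) {
    stop(path, ": expected columns wavelength_nm,intensity", call. = FALSE)
  }
  emission_spectrum(tab$wavelength_nm, tab$intensity)
}

#' Load a full experiment from a run config
#'
#' The config is a YAML file:
#' \preformatted{
#' mechanism: three_state       # registry name, or mechanism_file: <yaml>
#' seed: 1
#' datasets:
#'   - path: ds01.csv              # tabulated signal vs urea
#'   - probe: AEW280               # or raw emission scans, reduced to AEW
#'     ph: 7
#'     conc_uM: 4
#'     spectra:
#'       - {path: scan_u0.csv, urea_M: 0}
#'       - {path: scan_u9.csv, urea_M: 9}
#' fit:
#'   n_starts: 6
#' }
#' Relative dataset paths resolve against the config's directory.  Raw
#' spectra are reduced with [average_emission_wavelength()].  All datasets
#' are validated (urea range, pH consistency across datasets).
#'
#' @param config path to the YAML run config, or an equivalent list.
#' @param base_dir directory for resolving relative paths (defaults to the
#'   config file's directory).
#' @return a [fit_spec()].
#' @export
load_experiment <- function(config, base_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("no such config file: ", config, call. = FALSE)
    }
    if (is.null(base_dir)) base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(base_dir)) base_dir <- "."
  resolve <- function(p) {
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  if (is.null(config$mechanism) && is.null(config$mechanism_file)) {
    stop("config must name a registry mechanism or a mechanism_file",
         call. = FALSE)
  }
  mech <- if (!is.null(config$mechanism_file)) {
    read_mechanism_config(resolve(config$mechanism_file))$mechanism
  } else {
    get_mechanism(config$mechanism)
  }
  if (is.null(config$datasets) || length(config$datasets) == 0L) {
    stop("config lists no datasets", call. = FALSE)
  }
  datasets <- lapply(config$datasets, function(entry) {
    if (!is.null(entry$path)) {
      p <- resolve(entry$path)
      if (!file.exists(p)) {
        stop("dataset file not found: ", entry$path, call. = FALSE)
      }
      read_unfolding_csv(p)
    } else if (!is.null(entry$spectra)) {
      urea <- vapply(entry$spectra, function(s) as.numeric(s$urea_M), 0)
      aew <- vapply(entry$spectra, function(s) {
        p <- resolve(s$path)
        if (!file.exists(p)) {
          stop("spectrum file not found: ", s$path, call. = FALSE)
        }
        average_emission_wavelength(read_emission_csv(p))
      }, 0)
      o <- order(urea)
      unfolding_dataset(
        urea[o], aew[o], probe = entry$probe, ph = as.numeric(entry$ph),
        conc_uM = as.numeric(entry$conc_uM),
        direction = if (is.null(entry$direction)) "unfolding"
                    else entry$direction
      )
    } else {
      stop("each dataset entry needs either `path` or `spectra`",
           call. = FALSE)
    }
  })
  opt_args <- c(config$fit,
                if (!is.null(config$seed)) list(seed = config$seed))
  opts <- do.call(fit_options, as.list(opt_args))
  init <- NULL
  if (!is.null(config$init)) {
    init <- thermo_params(as.numeric(config$init$dG0),
                          as.numeric(config$init$m))
  }
  fit_spec(mech, datasets, init = init, options = opts)
}

# report column index (1..3) of each transition, matching the standard
# table layout: native isomerization -> 1, second dimer isomerization -> 2,
# dissociation -> 3; other chains fall back to sequential positions
.report_columns <- function(mech) {
  tr <- mech$transitions
  col <- integer(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    col[i] <- if (tr$from[i] == "N2" && tr$to[i] == "I2") 1L
      else if (tr$from[i] == "I2" && tr$to[i] == "I2p") 2L
      else if (tr$type[i] == "dissociation") 3L
      else NA_integer_
  }
  if (anyNA(col) || anyDuplicated(col[!is.na(col)])) {
    col <- seq_len(nrow(tr))
  }
  col
}

#' Parameter table of a fit in the standard report layout
#'
#' One row per fit: pH, then dG/m (and their standard errors) in three stage
#' columns — native isomerization, second dimer isomerization, dissociation —
#' plus totals.  Stages absent from the mechanism are left `NA`, mirroring
#' the blank cells of a multi-pH summary table.
#'
#' @param result a [global_fit()] result.
#' @return one-row data.frame.
#' @export
parameter_table <- function(result) {
  stopifnot(inherits(result, "fit_result"))
  k <- length(result$estimates$dG0)
  cols <- .report_columns(result$mechanism)
  dG <- se_dG <- m <- se_m <- rep(NA_real_, 3L)
  for (i in seq_len(k)) {
    dG[cols[i]] <- result$estimates$dG0[i]
    m[cols[i]] <- result$estimates$m[i]
    se_dG[cols[i]] <- result$standard_errors[i]
    se_m[cols[i]] <- result$standard_errors[k + i]
  }
  tot <- total_free_energy(result$estimates)
  data.frame(
    ph = result$ph,
    dG1 = dG[1L], dG1_se = se_dG[1L], m1 = m[1L], m1_se = se_m[1L],
    dG2 = dG[2L], dG2_se = se_dG[2L], m2 = m[2L], m2_se = se_m[2L],
    dG3 = dG[3L], dG3_se = se_dG[3L], m3 = m[3L], m3_se = se_m[3L],
    dG_total = tot[["dG_total"]], m_total = tot[["m_total"]]
  )
}

#' Write the report bundle of a global fit
#'
#' Emits, under `outdir`: `parameters.csv` (the standard stage-column
#' layout, totals equal to the sum of the stage columns), one
#' `residuals_NN.csv` per dataset (urea, observed, fitted, residual),
#' one `fractions_<Pt>uM.csv` per population profile and a machine-readable
#' `manifest.json` (mechanism, seed, objective, convergence, config hash).
#' All numeric fields are written at 17 significant digits.
#'
#' @param result a converged [global_fit()] result.
#' @param profiles optional list of [population_profile()] objects.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the written paths and in-memory tables.
#' @export
write_report <- function(result, profiles = NULL, outdir = ".") {
  stopifnot(inherits(result, "fit_result"))
  if (!result$converged) {
    stop("refusing to write a report for a non-converged fit", call. = FALSE)
  }
  if (!dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  write_num_csv <- function(tab, path) {
    out <- as.data.frame(lapply(tab, function(col) {
      if (is.numeric(col)) .fmt17(col) else as.character(col)
    }))
    names(out) <- names(tab)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    path
  }
  paths <- list()
  ptab <- parameter_table(result)
  paths$parameters <- write_num_csv(ptab, file.path(outdir, "parameters.csv"))
  for (j in seq_along(result$datasets)) {
    d <- result$datasets[[j]]
    tab <- data.frame(urea_M = d$urea, signal = d$signal,
                      fitted = result$fitted[[j]],
                      residual = result$residuals[[j]])
    paths$residuals <- c(
      paths$residuals,
      write_num_csv(tab, file.path(outdir, sprintf("residuals_%02d.csv", j)))
    )
  }
  if (!is.null(profiles)) {
    for (pr in profiles) {
      tab <- as.data.frame(pr)
      f <- file.path(outdir, sprintf("fractions_%guM.csv",
                                     pr$total_protomer * 1e6))
      paths$fractions <- c(paths$fractions, write_num_csv(tab, f))
    }
  }
  cfg_string <- paste(
    result$mechanism$name, result$ph, result$seed,
    paste(.fmt17(c(result$estimates$dG0, result$estimates$m)), collapse = ","),
    sep = "|"
  )
  tf <- tempfile()
  writeLines(cfg_string, tf)
  manifest <- list(
    mechanism = result$mechanism$name, ph = result$ph, seed = result$seed,
    n_datasets = length(result$datasets),
    n_refolding = result$n_refolding,
    objective = result$objective, converged = result$converged,
    n_evaluations = result$n_evaluations,
    config_hash = unname(tools::md5sum(tf)),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("dimerfold"))
  )
  unlink(tf)
  paths$manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = paths, parameters = ptab))
}
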