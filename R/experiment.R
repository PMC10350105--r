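#' Run the full simulate / fit / P-VAE experiment
#'
#' End-to-end driver: simulates a dataset under the configuration, runs the
#' classical edge-shift fit (with a profile-likelihood interval) and the
#' P-VAE, compares both against the ground-truth sidecar, and assembles a
#' report. When `out_dir` is given, the dataset bundle, truth sidecar,
#' reflection table, recovered curve, report JSON and diagnostic plots
#' (curve overlay, posterior histogram) are written there. The report
#' contains no timestamps, so a rerun with identical config and seed
#' produces byte-identical files.
#'
#' @param config experiment configuration (see [default_config()]).
#' @param out_dir optional output directory (created if missing).
#' @param run_pvae run the P-VAE stage (TRUE by default).
#' @param interval_method interval for the classical fit
#'   (`"profile"` or `"bootstrap"`).
#' @return report list (class `spread_report`), invisibly when writing.
#' @export
run_experiment <- function(config = default_config(), out_dir = NULL,
                           run_pvae = TRUE,
                           interval_method = "profile") {
  config <- validate_config(config)
  hash <- config_hash(config)
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  sim <- stage("simulate", simulate_dataset(config, seed = seed))
  design <- stage("design", build_design(sim$data))
  fit <- stage("fit", fit_edge_shift(design, config = config))
  ci <- stage("fit_interval",
              edge_shift_interval(fit, method = interval_method))
  fit$edge_shift_ci <- as.numeric(ci)
  pv <- NULL; post <- NULL
  if (run_pvae) {
    pv <- stage("pvae", train_pvae(design, config, seed = seed + 1))
    post <- stage("pvae_posterior", sample_posterior(pv, n = 2000,
                                                     seed = seed + 2))
  }
  truth_shift <- sim$truth$edge_shift
  report <- list(
    provenance = list(config_hash = hash, seed = seed,
                      package_version = as.character(
                        utils::packageVersion("sfxspread"))),
    dataset = list(n_shots = length(sim$data$shots),
                   n_shoeboxes = design$n_sb,
                   model_error = config$model_error),
    truth = list(edge_shift_ev = truth_shift),
    classic_fit = list(
      edge_shift_ev = fit$params$edge_shift,
      interval_ev = as.numeric(ci),
      interval_method = interval_method,
      error_ev = fit$params$edge_shift - truth_shift,
      nll = fit$nll,
      converged = fit$converged,
      loss_trace_range = range(fit$loss_trace)),
    pvae = if (run_pvae) list(
      edge_shift_mean_ev = pv$posterior$edge_shift_mean,
      edge_shift_sd_ev = pv$posterior$edge_shift_sd,
      interval90_ev = c(post$summary$q05, post$summary$q95),
      error_ev = pv$posterior$edge_shift_mean - truth_shift,
      final_loss = unname(pv$trace[length(pv$trace)]),
      heldout_deviance = if (!is.null(pv$val_design))
        pvae_heldout_deviance(pv$model, pv$val_design) else NA_real_)
  )
  class(report) <- "spread_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_dataset(sim$data, file.path(out_dir, "data.rds"))
    write_truth_sidecar(sim$truth, file.path(out_dir, "truth.rds"))
    write_reflection_table(sim$data, file.path(out_dir, "reflections.csv"))
    write_anomalous_curve(
      shift_edge(sim$data$reference_curve, fit$params$edge_shift),
      file.path(out_dir, "recovered_curve.txt"))
    write_report(report, file.path(out_dir, "report.json"))
    plot_curve_overlay(sim$data$reference_curve, sim$truth$true_curve,
                       fit$params$edge_shift,
                       file.path(out_dir, "curves.png"))
    if (run_pvae)
      plot_posterior_hist(post$edge_shift, truth_shift,
                          file.path(out_dir, "posterior.png"))
    return(invisible(report))
  }
  report
}

#' @export
print.spread_report <- function(x, ...) {
  cat(sprintf("<spread_report> config %s, seed %d\n",
              x$provenance$config_hash, x$provenance$seed))
  cat(sprintf("  truth      %+.3f eV\n", x$truth$edge_shift_ev))
  cat(sprintf("  classic    %+.3f eV  [%+.3f, %+.3f]\n",
              x$classic_fit$edge_shift_ev, x$classic_fit$interval_ev[1],
              x$classic_fit$interval_ev[2]))
  if (!is.null(x$pvae))
    cat(sprintf("  pvae       %+.3f +/- %.3f eV\n",
                x$pvae$edge_shift_mean_ev, x$pvae$edge_shift_sd_ev))
  invisible(x)
}

#' Write a run report as JSON
#'
#' @param report a `spread_report` (or any list).
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

plot_curve_overlay <- function(ref, true_curve, fitted_shift, path) {
  grDevices::png(path, width = 800, height = 500)
  on.exit(grDevices::dev.off())
  e <- as.numeric(ref$grid)
  rec <- shift_edge(ref, fitted_shift)
  graphics::matplot(e, cbind(true_curve$f_prime, rec$f_prime,
                             true_curve$f_double_prime, rec$f_double_prime),
                    type = "l", lty = c(1, 2, 1, 2),
                    col = c("black", "red", "grey40", "orange"),
                    xlab = "energy (eV)", ylab = "electrons",
                    main = "anomalous curves: truth (solid) vs recovered (dashed)")
  graphics::legend("topleft", c("f' true", "f' recovered",
                                "f'' true", "f'' recovered"),
                   lty = c(1, 2, 1, 2),
                   col = c("black", "red", "grey40", "orange"), bty = "n")
}

plot_posterior_hist <- function(draws, truth, path) {
  grDevices::png(path, width = 600, height = 450)
  on.exit(grDevices::dev.off())
  graphics::hist(draws, breaks = 40, col = "grey80", border = "white",
                 xlab = "edge shift (eV)",
                 main = "P-VAE posterior over the edge shift")
  graphics::abline(v = truth, col = "red", lwd = 2)
}
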