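#' Run the full analysis workflow on files
#'
#' Reads a count CSV and control regions, fits the model (with automatic
#' choice of the number of functional sequences unless `K` is given), and
#' writes the output bundle to `out_dir`: one bedGraph per functional
#' sequence plus the combined probability track, a BED6 of credible
#' regions, the full probability matrix as CSV, and a K-selection
#' diagnostics CSV. Configuration values actually used (defaults made
#' explicit) are logged via `message()`.
#'
#' @param counts_csv path to the input count CSV.
#' @param controls control regions (path, strings, or data.frame).
#' @param out_dir output directory.
#' @param ... model options passed to [fs_screen()].
#' @return The [fs_screen] fit, invisibly, with the written paths in
#'   attribute `"files"`.
#' @export
run_pipeline <- function(counts_csv, controls, out_dir, ...) {
  fit <- fs_screen(counts_csv, controls, ...)
  for (nm in names(fit$params))
    message("config: ", nm, " = ", paste(fit$params[[nm]], collapse = ","))
  message("alpha0 = ", paste(signif(fit$fit$model$alpha0, 4),
                             collapse = ", "))
  message("alpha1 = ", paste(signif(fit$fit$model$alpha1, 4),
                             collapse = ", "))
  message("selected K = ", nrow(fit$fit$pi) - 1L,
          " after ", fit$fit$n_iter, " iteration(s)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- write_probability_tracks(fit$fit$pi, fit$segmap, out_dir)
  bed <- file.path(out_dir, "credible_regions.bed")
  write_fs_regions(fit$regions, bed)
  pi_csv <- file.path(out_dir, "probability_matrix.csv")
  write_pi_csv(fit$fit$pi, fit$segmap, pi_csv)
  files <- c(files, bed, pi_csv)
  if (!is.null(fit$selection)) {
    diag_csv <- file.path(out_dir, "k_selection.csv")
    write.csv(fit$selection$diagnostics, diag_csv, row.names = FALSE)
    files <- c(files, diag_csv)
  }
  attr(fit, "files") <- files
  invisible(fit)
}

#' Simulate, analyse and score a screen end to end
#'
#' Smoke-test workflow: simulates a preset screen, analyses it with the
#' positive-control element as the control region, and scores the result
#' against the simulated truth.
#'
#' @param preset preset name for [sim_preset()] (default `"facs_small"`).
#' @param seed integer seed controlling every random step.
#' @param out_dir optional directory for the output bundle; when NULL,
#'   nothing is written.
#' @param sim_args list of overrides for [sim_preset()].
#' @param control_pad bp added on each side of the positive-control element
#'   when forming the control region (default 1000). This mirrors the
#'   promoter-region convention of experimental analyses (TSS +/- 1 kb):
#'   the control region should cover all guides whose area of effect is
#'   dominated by the known element, not just the element's own bases.
#' @param ... analysis options passed to [fs_screen()].
#' @return One-row metrics data.frame (see [evaluate_fit()]) with the
#'   selected K in column `K`; the fit is in attribute `"fit"` and the
#'   simulation in attribute `"sim"`.
#' @export
end_to_end_smoke <- function(preset = "facs_small", seed = 1,
                             out_dir = NULL, sim_args = list(),
                             control_pad = 1000, ...) {
  config <- do.call(sim_preset, c(list(name = preset, seed = seed),
                                  sim_args))
  sim <- simulate_screen(config)
  controls <- sim$truth$fs0
  controls$start <- pmax(0, controls$start - control_pad)
  controls$end <- controls$end + control_pad
  fit <- fs_screen(sim$data, controls, ...)
  metrics <- evaluate_fit(fit$fit, sim$truth, coverage = fit$coverage)
  metrics$K <- nrow(fit$fit$pi) - 1L
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_screen_counts(sim$data, file.path(out_dir, "counts.csv"))
    write.csv(metrics, file.path(out_dir, "metrics.csv"),
              row.names = FALSE)
  }
  attr(metrics, "fit") <- fit
  attr(metrics, "sim") <- sim
  metrics
}
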