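#' Fit the functional-sequence model to a tiling screen
#'
#' The top-level fitting interface. Tiles the screened region into genome
#' segments, anchors the positive-control row from the supplied control
#' regions, and runs iterative Bayesian stepwise selection -- either at a
#' fixed number of functional sequences `K`, or (default) choosing K by
#' the pairwise-correlation criterion of [select_k()].
#'
#' @param counts a [screen_data] object or path to a count CSV readable by
#'   [read_screen_counts()].
#' @param controls known functional-sequence (positive-control) regions in
#'   any form accepted by [parse_regions()].
#' @param segment_size genome segment width in bp (default 100).
#' @param effect_range analysis area of effect added each side of a target
#'   site (default 200, i.e. 400 bp total for CRISPRi/CRISPRa; use ~10 for
#'   Cas9).
#' @param lambda,L truncated-geometric length-prior parameters.
#' @param K fixed number of functional sequences; `NULL` (default) selects
#'   K automatically.
#' @param k_max,corr_threshold K-selection bounds (defaults 20 and 0.1).
#' @param tol,max_iter stepwise-selection convergence controls.
#' @param coverage credible-region coverage (default 0.95).
#' @param exclude_fs0 exclude positive-control segments from candidate
#'   placements (default TRUE).
#' @param model optional fixed [sorting_model]; when supplied the
#'   hyperparameters are not re-estimated.
#' @param diffuse_width regions spanning more than this many segments are
#'   flagged as diffuse/unsupported in the summary (default 50).
#'
#' @return An object of class `"fs_screen"` with components `fit` (the
#'   [ibss_fit]), `selection` (K diagnostics or NULL), `regions`
#'   (credible regions), `segmap`, `pi0`, and the call. Methods: `print`,
#'   `summary`, `coef` (sorting shapes), `fitted` (per-segment combined
#'   probability), `plot`, `predict`.
#' @seealso [run_pipeline()] for the file-to-file workflow.
#' @export
fs_screen <- function(counts, controls, segment_size = 100,
                      effect_range = 200, lambda = 0.1, L = 10, K = NULL,
                      k_max = 20, corr_threshold = 0.1, tol = 1e-3,
                      max_iter = 100, coverage = 0.95, exclude_fs0 = TRUE,
                      model = NULL, diffuse_width = 50) {
  cl <- match.call()
  data <- if (inherits(counts, "screen_data")) counts
          else read_screen_counts(counts)
  segmap <- build_segment_map(data, segment_size, effect_range)
  pi0 <- mark_fs0(segmap, controls)
  prior <- length_prior(lambda, L)
  refit <- is.null(model)
  if (is.null(K)) {
    selection <- select_k(data, segmap, pi0, prior = prior, k_max = k_max,
                          corr_threshold = corr_threshold, tol = tol,
                          max_iter = max_iter, exclude_fs0 = exclude_fs0,
                          model = model, refit_model = refit)
    fit <- selection$fit
  } else {
    selection <- NULL
    fit <- ibss_fit(data, segmap, pi0, K, prior = prior, tol = tol,
                    max_iter = max_iter, exclude_fs0 = exclude_fs0,
                    model = model, refit_model = refit)
  }
  regions <- credible_regions(fit, coverage)
  regions$diffuse <- (regions$end - regions$start) / segment_size >
    diffuse_width
  structure(list(call = cl, data = data, segmap = segmap, pi0 = pi0,
                 prior = prior, selection = selection, fit = fit,
                 regions = regions, coverage = coverage,
                 params = list(segment_size = segment_size,
                               effect_range = effect_range,
                               lambda = lambda, L = L, k_max = k_max,
                               corr_threshold = corr_threshold, tol = tol,
                               max_iter = max_iter, coverage = coverage,
                               exclude_fs0 = exclude_fs0,
                               diffuse_width = diffuse_width)),
            class = "fs_screen")
}

#' @export
print.fs_screen <- function(x, ...) {
  cat("Tiling-screen functional sequence fit\n")
  cat("Call: ", deparse(x$call), "\n\n")
  K <- nrow(x$fit$pi) - 1L
  cat(nrow(x$data$counts), "sgRNAs,", ncol(x$data$counts), "pools,",
      x$segmap$M, "segments of", x$segmap$segment_size, "bp\n")
  cat("K =", K, if (is.null(x$selection)) "(fixed)"
      else "(selected by pairwise correlation)", "\n")
  cat(nrow(x$regions), "credible region(s) at", x$coverage, "coverage\n")
  invisible(x)
}

#' @method summary fs_screen
#' @export
summary.fs_screen <- function(object, ...) {
  structure(list(object = object), class = "summary.fs_screen")
}

#' @export
print.summary.fs_screen <- function(x, ...) {
  obj <- x$object
  print(obj)
  cat("\n")
  print(obj$fit$model)
  if (!is.null(obj$selection)) {
    cat("\nK selection diagnostics:\n")
    print(obj$selection$diagnostics, row.names = FALSE)
  }
  cat("\nCredible regions (", obj$coverage, " coverage):\n", sep = "")
  print(obj$regions, row.names = FALSE)
  if (any(obj$regions$diffuse))
    cat("note:", sum(obj$regions$diffuse), "region(s) are diffuse (wider ",
        "than", obj$params$diffuse_width, "segments) and likely ",
        "unsupported\n")
  invisible(x)
}

#' @export
coef.fs_screen <- function(object, ...) {
  rbind(alpha0 = object$fit$model$alpha0, alpha1 = object$fit$model$alpha1)
}

#' @export
fitted.fs_screen <- function(object, ...) {
  pmin(1, pmax(0, colSums(object$fit$pi)))
}

#' Per-interval functional probability
#'
#' For each query interval, the maximum combined per-segment functional
#' probability over the segments it overlaps.
#'
#' @param object an [fs_screen] fit.
#' @param newdata intervals in any [parse_regions()] form; default: the
#'   fitted credible regions.
#' @param ... unused.
#' @return Numeric vector, one probability per interval.
#' @export
predict.fs_screen <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$regions
  gr <- parse_regions(newdata)
  p <- fitted(object)
  ov <- findOverlaps(gr, segment_ranges(object$segmap))
  out <- numeric(length(gr))
  if (length(ov) > 0) {
    agg <- tapply(p[subjectHits(ov)], queryHits(ov), max)
    out[as.integer(names(agg))] <- agg
  }
  out
}

#' Plot the fitted probability landscape
#'
#' Base-graphics track of the combined per-segment functional probability
#' along the genome, with the positive-control segments shaded and the
#' credible regions marked.
#'
#' @param x an [fs_screen] fit.
#' @param truth optional true intervals (e.g. `truth$fs`) drawn as ticks.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fs_screen <- function(x, truth = NULL, ...) {
  segs <- x$segmap$segments
  mid <- (segs$start + segs$end) / 2
  p <- fitted(x)
  plot(mid, p, type = "h", col = "grey40", ylim = c(0, 1),
       xlab = paste0("position on ", segs$chrom[1], " (bp)"),
       ylab = "Pr(segment contains a functional sequence)", ...)
  fs0 <- which(x$pi0 > 0)
  if (length(fs0) > 0)
    rect(segs$start[fs0], 0, segs$end[fs0], 1,
         col = grDevices::adjustcolor("steelblue", 0.2), border = NA)
  if (nrow(x$regions) > 0)
    segments(x$regions$start, 1.0, x$regions$end, 1.0, col = "firebrick",
             lwd = 3)
  if (!is.null(truth))
    points((truth$start + truth$end) / 2, rep(0, nrow(truth)), pch = 17,
           col = "darkgreen")
  invisible(x)
}
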