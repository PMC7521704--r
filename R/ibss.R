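#' Truncated-geometric prior over functional-sequence lengths
#'
#' Prior weight for a functional sequence of length l segments:
#' `w_l = (1-lambda)^(l-1) * lambda / sum_{i=1..L} (1-lambda)^(i-1) * lambda`,
#' a geometric distribution truncated at the maximum length L. The prior is
#' uniform across all placements sharing the same length, so the prior
#' probability of a specific placement of length l is `w_l` divided by the
#' number of valid length-l placements.
#'
#' @param lam geometric parameter in (0, 1); larger values favour shorter
#'   elements more strongly.
#' @param L maximum length in segments (default 10).
#' @return An object of class `"length_prior"` with elements `lambda`, `L`
#'   and the normalised weight vector `w`.
#' @export
length_prior <- function(lam = 0.1, L = 10) {
  if (!is.finite(lam) || lam <= 0 || lam >= 1)
    stop_tilefs("lambda must lie strictly in (0, 1)",
                class = "tilefs_domain_error")
  if (L < 1) stop_tilefs("L must be >= 1", class = "tilefs_domain_error")
  w <- (1 - lam)^(seq_len(L) - 1) * lam
  structure(list(lambda = lam, L = as.integer(L), w = w / sum(w)),
            class = "length_prior")
}

#' @export
print.length_prior <- function(x, ...) {
  cat("Truncated geometric length prior: lambda =", x$lambda,
      ", L =", x$L, "\n")
  cat("  w =", paste(signif(x$w, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Number of unordered single-segment configurations
#'
#' Exact count of the distinct ways to place `K` single-segment functional
#' sequences among `M` genome segments (unordered, no two in the same
#' segment): the binomial coefficient choose(M, K). Illustrates why
#' enumerating all configurations is intractable and stepwise placement is
#' needed.
#'
#' @param M number of genome segments.
#' @param K number of functional sequences.
#' @return choose(M, K) as a double.
#' @export
n_configurations <- function(M, K) {
  choose(M, K)
}

# Enumerate all valid placements (m = start segment, l = length) given a
# segment map, max length L, and an optional logical exclusion mask over
# segments. Placements never span chromosome runs or cover excluded
# segments.
enumerate_placements <- function(segmap, L, exclude = NULL) {
  M <- segmap$M
  run <- segmap$run
  if (is.null(exclude)) exclude <- rep(FALSE, M)
  ms <- integer(0); ls <- integer(0)
  for (l in seq_len(L)) {
    m <- seq_len(M - l + 1L)
    if (length(m) == 0) break
    ok <- run[m] == run[m + l - 1L]
    if (any(exclude)) {
      # a placement is invalid if it covers any excluded segment
      cum_ex <- cumsum(exclude)
      covered <- cum_ex[m + l - 1L] - c(0, cum_ex)[m]
      ok <- ok & covered == 0
    }
    ms <- c(ms, m[ok]); ls <- c(ls, rep(l, sum(ok)))
  }
  if (length(ms) == 0)
    stop_tilefs("no valid placements (region fully excluded?)",
                class = "tilefs_config_error")
  data.frame(m = ms, l = ls, end = ms + ls - 1L)
}

#' Combined per-segment functional probability
#'
#' Probability that each genome segment contains any functional sequence:
#' `p_m = delta_m + (1 - delta_m) * min(1, sum_k pi[k, m])`, where delta is
#' the (optional) hard placement under consideration. Row sums exceeding 1
#' (possible when probabilistic placements overlap) are clipped so that p
#' remains a probability.
#'
#' @param pi (K+1) x M probability matrix (row 1 is the positive-control
#'   row), or a single row vector.
#' @param exclude_k optional functional-sequence index (1..K) whose row is
#'   zeroed before summing.
#' @param placement optional list/data.frame with `m` and `l` giving a hard
#'   placement whose segments get probability 1.
#' @return Numeric vector p of length M.
#' @export
segment_probability <- function(pi, exclude_k = NULL, placement = NULL) {
  pi <- rbind(pi)
  if (!is.null(exclude_k)) pi[exclude_k + 1L, ] <- 0
  p <- pmin(1, pmax(0, colSums(pi)))
  if (!is.null(placement))
    p[seq(placement$m, placement$m + placement$l - 1L)] <- 1
  p
}

#' Posterior over all placements of one functional sequence
#'
#' For every valid placement (start segment m, length l) of a functional
#' sequence, computes the likelihood of the full count table under the
#' Dirichlet-multinomial mixture -- conditioning on the probabilistic
#' placements of all other functional sequences -- and combines it with the
#' truncated-geometric placement prior into a normalised posterior.
#'
#' A placement sets its covered segments to probability 1, which forces
#' every guide overlapping it into the functional mixture component; guides
#' not overlapping the placement keep their baseline mixture term. The
#' default evaluation exploits this to update only the guides a placement
#' touches; `method = "naive"` re-evaluates the full product per placement
#' (identical result, used for verification).
#'
#' @param data a [screen_data] object.
#' @param segmap the matching [build_segment_map] result.
#' @param pi a (K+1) x M probability matrix; the row of the sequence being
#'   placed must be zero (or supply `exclude_k` to zero it).
#' @param model a fitted [sorting_model].
#' @param prior a [length_prior].
#' @param exclude_k optional index k whose row of `pi` is zeroed first.
#' @param exclude_segments optional logical mask of segments that may not be
#'   covered by a placement (e.g. the positive-control segments).
#' @param method `"incremental"` (default) or `"naive"`.
#' @return data.frame with columns `m`, `l`, `log_prior`, `log_lik`, `pp`
#'   (posterior probabilities summing to 1), with the log marginal
#'   likelihood in attribute `"log_evidence"`.
#' @export
placement_posteriors <- function(data, segmap, pi, model, prior,
                                 exclude_k = NULL, exclude_segments = NULL,
                                 method = c("incremental", "naive")) {
  method <- match.arg(method)
  pi <- rbind(pi)
  if (!is.null(exclude_k)) pi[exclude_k + 1L, ] <- 0
  placements <- enumerate_placements(segmap, prior$L, exclude_segments)
  Y <- data$counts
  storage.mode(Y) <- "double"
  d0 <- dmn_log_pmf_rows(Y, model$alpha0)
  d1 <- dmn_log_pmf_rows(Y, model$alpha1)
  p_base <- pmin(1, pmax(0, colSums(pi)))
  if (method == "incremental") {
    log_lik <- placement_logliks(segmap, placements, p_base, d0, d1)
  } else {
    log_lik <- vapply(seq_len(nrow(placements)), function(i) {
      p <- p_base
      p[placements$m[i]:placements$end[i]] <- 1
      q0 <- guide_zero_probs(segmap, p)
      sum(mixture_loglik_terms(d0, d1, q0))
    }, numeric(1))
  }
  n_l <- tabulate(placements$l, nbins = prior$L)
  log_prior <- log(prior$w[placements$l]) - log(n_l[placements$l])
  lp <- log_prior + log_lik
  if (all(!is.finite(lp)))
    stop_tilefs("all placements have zero likelihood",
                class = "tilefs_numeric_error")
  lse <- max(lp) + log(sum(exp(lp - max(lp))))
  out <- data.frame(m = placements$m, l = placements$l,
                    log_prior = log_prior, log_lik = log_lik,
                    pp = exp(lp - lse))
  attr(out, "log_evidence") <- lse
  out
}

# Fast placement log-likelihoods. For guides overlapping a placement the
# mixture term becomes exactly log DMN(y | alpha1); all other guides keep
# their baseline term. Since each guide's segment set is a contiguous run
# [a_n, b_n], the sum of per-guide gains over guides intersecting [m, e] is
# cumA(e) - cumB(m - 1) with suffix/prefix sums over a_n and b_n.
placement_logliks <- function(segmap, placements, p_base, d0, d1) {
  q0 <- guide_zero_probs(segmap, p_base)
  base <- mixture_loglik_terms(d0, d1, q0)
  gain <- d1 - base
  a <- vapply(segmap$g, `[`, integer(1), 1L)
  b <- vapply(segmap$g, function(s) s[length(s)], integer(1))
  M <- segmap$M
  sum_at <- function(idx) {
    v <- numeric(M)
    agg <- rowsum(gain, idx)
    v[as.integer(rownames(agg))] <- agg
    v
  }
  cumA <- cumsum(sum_at(a))          # sum of gains with a_n <= e
  cumB <- c(0, cumsum(sum_at(b)))    # cumB[m] = sum of gains with b_n <= m-1
  B <- sum(base)
  B + cumA[placements$end] - cumB[placements$m]
}

#' Project a placement posterior onto segments
#'
#' Per-segment probability that the functional sequence covers the segment:
#' the total posterior mass of all placements overlapping it,
#' `pi_k[m] = sum_l sum_{i = m-l+1..m} PP(i, l)`. The row total equals the
#' posterior expected element length and lies in \[1, L\].
#'
#' @param PP a [placement_posteriors] table.
#' @param M number of genome segments.
#' @return Numeric vector of length M.
#' @export
update_pi_row <- function(PP, M) {
  d <- numeric(M + 1L)
  agg_s <- rowsum(PP$pp, PP$m)
  d[as.integer(rownames(agg_s))] <- d[as.integer(rownames(agg_s))] +
    as.vector(agg_s)
  ends <- PP$m + PP$l
  agg_e <- rowsum(PP$pp, ends)
  d[as.integer(rownames(agg_e))] <- d[as.integer(rownames(agg_e))] -
    as.vector(agg_e)
  pmin(1, pmax(0, cumsum(d)[seq_len(M)]))
}

#' Iterative Bayesian stepwise selection of functional sequences
#'
#' Estimates the (K+1) x M functional-sequence probability matrix. Each
#' outer iteration first refits the sorting hyperparameters by maximum
#' likelihood given the current probabilities, then for k = 1..K zeroes row
#' k, computes the combined probability contributed by the other rows, and
#' replaces row k with the segment projection of the exact placement
#' posterior for sequence k. Iteration stops when the largest absolute
#' change in the matrix falls below `tol`.
#'
#' @param data a [screen_data] object.
#' @param segmap the matching [build_segment_map] result.
#' @param pi0 length-M positive-control row from [mark_fs0()].
#' @param K number of functional sequences to place (>= 1).
#' @param prior a [length_prior].
#' @param tol convergence threshold on `max(abs(pi' - pi))` (default 1e-3).
#' @param max_iter outer-iteration cap (default 100).
#' @param model optional fixed or warm-start [sorting_model].
#' @param refit_model if `FALSE`, `model` is used as-is and never refit.
#' @param pi_init optional K x M matrix of warm-start rows.
#' @param exclude_fs0 if `TRUE` (default), segments of the positive-control
#'   row may not be covered by new placements.
#'
#' @return An object of class `"ibss_fit"`: list with `pi` (the matrix, row
#'   names `FS0..FSK`), `model`, `pp` (list of per-sequence placement
#'   posterior tables at the final fit), `prior`, `loglik_trace`, `n_iter`,
#'   `converged`, `segmap`.
#' @export
ibss_fit <- function(data, segmap, pi0, K, prior = length_prior(),
                     tol = 1e-3, max_iter = 100, model = NULL,
                     refit_model = TRUE, pi_init = NULL,
                     exclude_fs0 = TRUE) {
  stopifnot(inherits(data, "screen_data"), inherits(segmap, "segment_map"),
            inherits(prior, "length_prior"))
  if (K < 1) stop_tilefs("K must be >= 1", class = "tilefs_config_error")
  M <- segmap$M
  if (length(pi0) != M)
    stop_tilefs("pi0 length does not match the segment map",
                class = "tilefs_config_error")
  if (all(pi0 == 0))
    stop_tilefs("pi0 is empty; at least one positive-control segment is ",
                "required", class = "tilefs_config_error")
  pi <- matrix(0, nrow = K + 1L, ncol = M,
               dimnames = list(paste0("FS", 0:K), NULL))
  pi[1, ] <- pi0
  if (!is.null(pi_init)) {
    pi_init <- rbind(pi_init)
    pi[1L + seq_len(nrow(pi_init)), ] <- pi_init
  }
  exclude <- if (exclude_fs0) pi0 > 0 else NULL
  placements <- enumerate_placements(segmap, prior$L, exclude)
  n_l <- tabulate(placements$l, nbins = prior$L)
  log_prior <- log(prior$w[placements$l]) - log(n_l[placements$l])
  Y <- data$counts
  storage.mode(Y) <- "double"
  loglik_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    pi_old <- pi
    if (refit_model) {
      model <- fit_sorting_params(data, segmap, pi, init = model)
      ll <- model$loglik
    } else {
      if (is.null(model))
        stop_tilefs("a sorting model is required when refit_model = FALSE",
                    class = "tilefs_config_error")
      ll <- screen_loglik(data, segmap, pi, model)
    }
    loglik_trace <- c(loglik_trace, ll)
    d0 <- dmn_log_pmf_rows(Y, model$alpha0)
    d1 <- dmn_log_pmf_rows(Y, model$alpha1)
    for (k in seq_len(K)) {
      pi[k + 1L, ] <- 0
      p_base <- pmin(1, pmax(0, colSums(pi)))
      log_lik <- placement_logliks(segmap, placements, p_base, d0, d1)
      lp <- log_prior + log_lik
      pp <- exp(lp - max(lp))
      pp <- pp / sum(pp)
      pi[k + 1L, ] <- update_pi_row(data.frame(m = placements$m,
                                               l = placements$l, pp = pp), M)
    }
    if (max(abs(pi - pi_old)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && is.finite(tol) && max_iter > 1)
    warning("stepwise selection did not converge in ", max_iter,
            " iterations")
  # Final per-sequence placement posteriors at the converged fit.
  pp_tables <- lapply(seq_len(K), function(k) {
    placement_posteriors(data, segmap, pi, model, prior, exclude_k = k,
                         exclude_segments = exclude)
  })
  structure(list(pi = pi, model = model, pp = pp_tables, prior = prior,
                 loglik_trace = loglik_trace, n_iter = iter,
                 converged = converged, segmap = segmap,
                 exclude_fs0 = exclude_fs0),
            class = "ibss_fit")
}

#' @export
print.ibss_fit <- function(x, ...) {
  K <- nrow(x$pi) - 1L
  cat("Stepwise functional-sequence fit: K =", K, "sequences over",
      ncol(x$pi), "segments\n")
  cat("  ", x$n_iter, "iteration(s);",
      if (x$converged) "converged" else "NOT converged", "\n")
  print(x$model)
  invisible(x)
}

#' Choose the number of functional sequences
#'
#' Fits the model for K = 1, 2, ... and computes, at each K, all pairwise
#' Pearson correlations between the K estimated probability rows (the
#' positive-control row is excluded; a zero-variance row contributes
#' correlation 0). Once K exceeds the number of distinct functional
#' sequences supported by the data, newly added sequences co-locate with
#' existing ones and the maximum pairwise correlation jumps; the selected K
#' is the largest value whose maximum pairwise correlation is below
#' `corr_threshold`.
#'
#' @inheritParams ibss_fit
#' @param k_max largest K to consider (default 20).
#' @param corr_threshold correlation threshold (default 0.1).
#' @param warm_start reuse the K-1 fit's rows to initialise the K fit
#'   (default TRUE); set FALSE for cold starts at every K.
#' @param ... passed on to [ibss_fit()].
#' @return An object of class `"k_selection"`: list with `K` (selected),
#'   `fit` (the [ibss_fit] at the selected K), and `diagnostics` (data.frame
#'   of K, max pairwise correlation, final log-likelihood, iterations).
#' @export
select_k <- function(data, segmap, pi0, prior = length_prior(),
                     k_max = 20, corr_threshold = 0.1, warm_start = TRUE,
                     model = NULL, refit_model = TRUE, ...) {
  if (k_max < 1) stop_tilefs("k_max must be >= 1",
                             class = "tilefs_config_error")
  best_fit <- NULL
  best_k <- 0L
  diagnostics <- data.frame(K = integer(0), max_corr = numeric(0),
                            loglik = numeric(0), n_iter = integer(0),
                            converged = logical(0))
  prev_fit <- NULL
  for (K in seq_len(k_max)) {
    pi_init <- if (warm_start && !is.null(prev_fit))
      prev_fit$pi[-1, , drop = FALSE] else NULL
    start_model <- if (warm_start && refit_model && !is.null(prev_fit))
      prev_fit$model else model
    fit <- ibss_fit(data, segmap, pi0, K, prior = prior,
                    model = start_model, refit_model = refit_model,
                    pi_init = pi_init, ...)
    mc <- max_pairwise_correlation(fit$pi[-1, , drop = FALSE])
    diagnostics <- rbind(diagnostics,
                         data.frame(K = K, max_corr = mc,
                                    loglik = tail(fit$loglik_trace, 1),
                                    n_iter = fit$n_iter,
                                    converged = fit$converged))
    if (mc >= corr_threshold) break
    best_fit <- fit
    best_k <- K
    prev_fit <- fit
  }
  if (best_k == k_max)
    warning("k_max = ", k_max, " reached without a correlation violation; ",
            "the true number of functional sequences may be larger")
  structure(list(K = best_k, fit = best_fit, diagnostics = diagnostics,
                 corr_threshold = corr_threshold),
            class = "k_selection")
}

# Max pairwise Pearson correlation between rows; zero-variance rows
# contribute 0; -Inf when fewer than 2 rows (so K = 1 always passes).
max_pairwise_correlation <- function(rows) {
  K <- nrow(rows)
  if (K < 2) return(-Inf)
  vars <- apply(rows, 1, stats::var)
  cm <- suppressWarnings(stats::cor(t(rows)))
  cm[!is.finite(cm)] <- 0
  cm[vars == 0, ] <- 0
  cm[, vars == 0] <- 0
  max(cm[upper.tri(cm)])
}

#' @export
print.k_selection <- function(x, ...) {
  cat("Selected K =", x$K, "functional sequences",
      "(max pairwise correlation threshold", x$corr_threshold, ")\n")
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

#' Credible regions for each functional sequence
#'
#' Greedily accumulates placements by descending posterior probability
#' (ties broken by smaller start, then smaller length) until the cumulative
#' posterior reaches `coverage`, and reports the union of covered segments
#' as genomic intervals (adjacent segments merged). These regions are the
#' discrete predictions suitable for follow-up validation.
#'
#' @param fit an [ibss_fit].
#' @param coverage cumulative posterior mass to capture, in (0, 1\]
#'   (default 0.95).
#' @return data.frame with columns `fs`, `chrom`, `start`, `end` (0-based
#'   half-open), `posterior` (mass of the placements in the region).
#' @export
credible_regions <- function(fit, coverage = 0.95) {
  stopifnot(inherits(fit, "ibss_fit"))
  if (coverage <= 0 || coverage > 1)
    stop_tilefs("coverage must lie in (0, 1]", class = "tilefs_domain_error")
  segs <- fit$segmap$segments
  out <- list()
  for (k in seq_along(fit$pp)) {
    PP <- fit$pp[[k]]
    ord <- order(-PP$pp, PP$m, PP$l)
    PP <- PP[ord, , drop = FALSE]
    keep <- PP$pp > 0
    PP <- PP[keep, , drop = FALSE]
    n_take <- match(TRUE, cumsum(PP$pp) >= coverage)
    if (is.na(n_take)) n_take <- nrow(PP)
    sel <- PP[seq_len(n_take), , drop = FALSE]
    covered <- sort(unique(unlist(Map(seq, sel$m, sel$m + sel$l - 1L))))
    grp <- cumsum(c(1L, diff(covered) != 1L))
    for (gi in unique(grp)) {
      idx <- covered[grp == gi]
      in_region <- sel$m >= idx[1] & sel$m <= idx[length(idx)]
      out[[length(out) + 1L]] <-
        data.frame(fs = k, chrom = segs$chrom[idx[1]],
                   start = segs$start[idx[1]],
                   end = segs$end[idx[length(idx)]],
                   posterior = sum(sel$pp[in_region]))
    }
  }
  if (length(out) == 0)
    return(data.frame(fs = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      posterior = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}
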