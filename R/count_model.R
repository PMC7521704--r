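#' Dirichlet-multinomial log-pmf
#'
#' Log-probability of a vector of pool counts under the Dirichlet-multinomial
#' (multivariate Polya) distribution, conditioning on the observed total.
#' This is the marginal of Multinomial(s) counts when the sorting
#' probabilities s follow Dirichlet(alpha); the Dirichlet shape parameters
#' jointly encode the expected pool proportions (alpha_j / sum(alpha)) and
#' the overdispersion (through the concentration sum(alpha)).
#'
#' @param y non-negative integer vector of counts, length J.
#' @param alpha strictly positive numeric vector of Dirichlet shapes,
#'   length J.
#' @return The log pmf (0 for an all-zero count vector).
#' @export
dmn_log_pmf <- function(y, alpha) {
  if (!is_count_vector(y))
    stop_tilefs("y must be non-negative integers", class = "tilefs_domain_error")
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop_tilefs("alpha must be strictly positive and finite",
                class = "tilefs_domain_error")
  if (length(y) != length(alpha))
    stop_tilefs("y and alpha must have the same length",
                class = "tilefs_domain_error")
  s <- sum(y)
  a <- sum(alpha)
  lgamma(s + 1) - sum(lgamma(y + 1)) + lgamma(a) - lgamma(s + a) +
    sum(lgamma(y + alpha) - lgamma(alpha))
}

# Vectorised DMN log-pmf for an N x J count matrix under one alpha.
dmn_log_pmf_rows <- function(Y, alpha) {
  s <- rowSums(Y)
  a <- sum(alpha)
  lgamma(s + 1) - rowSums(lgamma(Y + 1)) + lgamma(a) - lgamma(s + a) +
    rowSums(lgamma(sweep(Y, 2, alpha, "+"))) - sum(lgamma(alpha))
}

#' Poisson-binomial probability of zero successes
#'
#' Probability that none of a set of independent, non-identical Bernoulli
#' trials succeeds. Used for the number of functional segments overlapped by
#' a guide's area of effect: r ~ PoissonBinomial(p) and Pr(r = 0) is the
#' product of the per-segment failure probabilities.
#'
#' @param p numeric vector of per-trial success probabilities in \[0, 1\]
#'   (possibly empty, giving probability 1).
#' @return Pr(all trials fail).
#' @export
pb_zero_prob <- function(p) {
  if (length(p) > 0 && (any(!is.finite(p)) || any(p < 0) || any(p > 1)))
    stop_tilefs("probabilities must lie in [0, 1]",
                class = "tilefs_domain_error")
  prod(1 - p)
}

#' Sorting model (Dirichlet hyperparameters)
#'
#' @param alpha0 Dirichlet shapes for sgRNAs overlapping no functional
#'   sequence (background sorting).
#' @param alpha1 Dirichlet shapes for sgRNAs overlapping a functional
#'   sequence.
#' @return An object of class `"sorting_model"`.
#' @export
sorting_model <- function(alpha0, alpha1) {
  if (length(alpha0) != length(alpha1))
    stop_tilefs("alpha0 and alpha1 must have the same length",
                class = "tilefs_domain_error")
  if (any(!is.finite(c(alpha0, alpha1))) || any(c(alpha0, alpha1) <= 0))
    stop_tilefs("Dirichlet shapes must be strictly positive and finite",
                class = "tilefs_domain_error")
  structure(list(alpha0 = as.numeric(alpha0), alpha1 = as.numeric(alpha1)),
            class = "sorting_model")
}

#' @export
print.sorting_model <- function(x, digits = 3, ...) {
  cat("Sorting model (Dirichlet shapes over", length(x$alpha0), "pools)\n")
  cat("  alpha0 (background):", paste(signif(x$alpha0, digits),
                                      collapse = ", "), "\n")
  cat("  alpha1 (functional):", paste(signif(x$alpha1, digits),
                                      collapse = ", "), "\n")
  if (!is.null(x$loglik)) cat("  log-likelihood:", format(x$loglik), "\n")
  invisible(x)
}

#' Write / read sorting hyperparameters as YAML
#'
#' Allows fixed, user-supplied hyperparameters to be carried between runs.
#'
#' @param model a [sorting_model].
#' @param path YAML file path.
#' @return `write_sorting_model` returns `path` invisibly;
#'   `read_sorting_model` returns a [sorting_model].
#' @export
write_sorting_model <- function(model, path) {
  stopifnot(inherits(model, "sorting_model"))
  yaml::write_yaml(list(alpha0 = model$alpha0, alpha1 = model$alpha1), path)
  invisible(path)
}

#' @rdname write_sorting_model
#' @export
read_sorting_model <- function(path) {
  spec <- yaml::read_yaml(path)
  sorting_model(as.numeric(spec$alpha0), as.numeric(spec$alpha1))
}

#' Mixture log-likelihood of one guide's counts
#'
#' Log of
#' `Pr(r > 0 | p) * DMN(y | alpha1) + Pr(r = 0 | p) * DMN(y | alpha0)`,
#' where r is the Poisson-binomial number of functional segments overlapped
#' by the guide, evaluated with log-sum-exp.
#'
#' @param y_n pool count vector for the guide.
#' @param p_gn per-segment functional probabilities over the guide's
#'   segments g(n).
#' @param model a [sorting_model].
#' @return Log-likelihood of the guide's counts.
#' @export
guide_mixture_loglik <- function(y_n, p_gn, model) {
  stopifnot(inherits(model, "sorting_model"))
  q0 <- pb_zero_prob(p_gn)
  d0 <- dmn_log_pmf(y_n, model$alpha0)
  d1 <- dmn_log_pmf(y_n, model$alpha1)
  mixture_loglik_terms(d0, d1, q0)
}

# log( (1-q0) e^{d1} + q0 e^{d0} ), vectorised over guides.
mixture_loglik_terms <- function(d0, d1, q0) {
  lw0 <- ifelse(q0 > 0, log(q0), -Inf)
  lw1 <- ifelse(q0 < 1, log1p(-q0), -Inf)
  logsumexp2(lw1 + d1, lw0 + d0)
}

# Per-guide Pr(r_n = 0) given combined segment probabilities p (length M).
# Round-off in the segment projections can leave p an epsilon outside
# [0, 1]; clamp so the products stay probabilities.
guide_zero_probs <- function(segmap, p) {
  p <- pmin(1, pmax(0, p))
  vapply(segmap$g, function(idx) prod(1 - p[idx]), numeric(1))
}

#' Fit the sorting hyperparameters by maximum likelihood
#'
#' Estimates `alpha0` and `alpha1` by maximising the full-data mixture
#' log-likelihood, holding the functional-sequence probability matrix fixed
#' at its current estimate. Optimisation is quasi-Newton (L-BFGS-B) over the
#' log of the shape parameters, which enforces positivity without box
#' constraints on the natural scale.
#'
#' @param data a [screen_data] object.
#' @param segmap the matching [build_segment_map] result.
#' @param pi_hat current (K+1) x M functional-sequence probability matrix;
#'   row 1 is the fixed positive-control row and must have at least one
#'   nonzero entry.
#' @param init optional [sorting_model] used as the starting point; default
#'   is a method-of-moments start from the empirical pool proportions of
#'   control-overlapping vs remaining guides with concentration 10.
#' @param maxit,pgtol L-BFGS-B iteration cap and projected-gradient
#'   tolerance.
#' @return A [sorting_model] with attributes `loglik` (attained objective),
#'   `convergence`, and `counts` recorded in the object.
#' @export
fit_sorting_params <- function(data, segmap, pi_hat, init = NULL,
                               maxit = 500, pgtol = 1e-6) {
  stopifnot(inherits(data, "screen_data"), inherits(segmap, "segment_map"))
  pi_hat <- rbind(pi_hat) # allow a bare pi0 vector
  if (ncol(pi_hat) != segmap$M)
    stop_tilefs("pi_hat has ", ncol(pi_hat), " columns but the map has ",
                segmap$M, " segments", class = "tilefs_config_error")
  if (all(pi_hat[1, ] == 0))
    stop_tilefs("the positive-control row of pi_hat is empty; ",
                "both mixture components need weight",
                class = "tilefs_config_error")
  Y <- data$counts
  storage.mode(Y) <- "double"
  J <- ncol(Y)
  p <- pmin(1, pmax(0, colSums(pi_hat)))
  q0 <- guide_zero_probs(segmap, p)
  if (all(q0 == 1))
    stop_tilefs("no guide overlaps a segment with nonzero functional ",
                "probability", class = "tilefs_config_error")
  zero_pool <- colSums(Y) == 0
  if (any(zero_pool))
    warning("pool(s) with all-zero counts: ",
            paste(colnames(Y)[zero_pool], collapse = ", "),
            "; their shapes are floored at a small positive constant")
  if (is.null(init)) {
    fs_like <- q0 < 0.5
    prop1 <- colSums(Y[fs_like, , drop = FALSE])
    prop0 <- colSums(Y[!fs_like, , drop = FALSE])
    if (sum(prop0) == 0) prop0 <- rep(1, J)
    if (sum(prop1) == 0) prop1 <- prop0
    init <- sorting_model(pmax(1e-3, 10 * prop0 / sum(prop0)),
                          pmax(1e-3, 10 * prop1 / sum(prop1)))
  }
  theta0 <- log(c(init$alpha0, init$alpha1))
  lw0 <- ifelse(q0 > 0, log(q0), -Inf)
  lw1 <- ifelse(q0 < 1, log1p(-q0), -Inf)
  negll <- function(theta) {
    a0 <- exp(theta[1:J]); a1 <- exp(theta[J + 1:J])
    d0 <- dmn_log_pmf_rows(Y, a0)
    d1 <- dmn_log_pmf_rows(Y, a1)
    -sum(logsumexp2(lw1 + d1, lw0 + d0))
  }
  grad <- function(theta) {
    a0 <- exp(theta[1:J]); a1 <- exp(theta[J + 1:J])
    d0 <- dmn_log_pmf_rows(Y, a0)
    d1 <- dmn_log_pmf_rows(Y, a1)
    tot <- logsumexp2(lw1 + d1, lw0 + d0)
    r1 <- exp(lw1 + d1 - tot)
    r0 <- 1 - r1
    s <- rowSums(Y)
    g_alpha <- function(a, resp) {
      A <- sum(a)
      common <- resp * (digamma(A) - digamma(s + A))
      percat <- crossprod(resp, digamma(sweep(Y, 2, a, "+"))) -
        sum(resp) * digamma(a)
      -(sum(common) + as.numeric(percat)) * a
    }
    c(g_alpha(a0, r0), g_alpha(a1, r1))
  }
  bounds <- c(log(1e-6), log(1e8))
  opt <- optim(theta0, negll, grad, method = "L-BFGS-B",
               lower = bounds[1], upper = bounds[2],
               control = list(maxit = maxit, pgtol = pgtol))
  if (opt$convergence == 1)
    warning("hyperparameter MLE hit the iteration cap; returning the best ",
            "iterate")
  # optim's ascent guarantee: never return something worse than the start.
  if (opt$value > negll(theta0) + 1e-9) {
    opt$par <- theta0
    opt$value <- negll(theta0)
    warning("optimizer failed to improve on the starting point")
  }
  fit <- sorting_model(exp(opt$par[1:J]), exp(opt$par[J + 1:J]))
  fit$loglik <- -opt$value
  fit$convergence <- opt$convergence
  fit$counts <- opt$counts
  fit
}

# Full-data mixture log-likelihood at a given pi matrix and model.
screen_loglik <- function(data, segmap, pi_hat, model) {
  Y <- data$counts
  storage.mode(Y) <- "double"
  p <- pmin(1, pmax(0, colSums(rbind(pi_hat))))
  q0 <- guide_zero_probs(segmap, p)
  d0 <- dmn_log_pmf_rows(Y, model$alpha0)
  d1 <- dmn_log_pmf_rows(Y, model$alpha1)
  sum(mixture_loglik_terms(d0, d1, q0))
}
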