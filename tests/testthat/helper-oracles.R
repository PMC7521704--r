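# Independent oracles and small fixture builders used across tests.
# These deliberately avoid the package's internal code paths: the DMN pmf
# uses gamma()/factorial() directly on small counts, the Poisson binomial
# enumerates subsets, and the exact placement posterior multiplies
# per-guide mixtures placement by placement.

# Direct multivariate Polya pmf (small counts only).
oracle_dmn <- function(y, alpha) {
  s <- sum(y)
  a <- sum(alpha)
  coef <- factorial(s) / prod(factorial(y))
  coef * gamma(a) / gamma(s + a) * prod(gamma(y + alpha) / gamma(alpha))
}

# Pr(r = 0) by enumerating all 2^n indicator outcomes.
oracle_pb_zero <- function(p) {
  n <- length(p)
  if (n == 0) return(1)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(bits) == 0)
      total <- total + prod(ifelse(bits == 1, p, 1 - p))
  }
  total
}

# All (m, l) placements on M segments with max length L (single run).
oracle_placements <- function(M, L, exclude = rep(FALSE, M)) {
  out <- NULL
  for (l in seq_len(L))
    for (m in seq_len(M - l + 1))
      if (!any(exclude[m:(m + l - 1)]))
        out <- rbind(out, data.frame(m = m, l = l))
  out
}

# Exact single-sequence placement posterior by full enumeration, using the
# oracle pmfs above. pi_other: probabilities contributed by all other rows
# (already summed and clipped). Returns pp in placement order.
oracle_placement_posterior <- function(counts, g, pi_other, alpha0, alpha1,
                                       w, exclude = NULL) {
  M <- length(pi_other)
  L <- length(w)
  pl <- oracle_placements(M, L, if (is.null(exclude)) rep(FALSE, M)
                                else exclude)
  n_l <- table(factor(pl$l, levels = seq_len(L)))
  lik <- numeric(nrow(pl))
  for (i in seq_len(nrow(pl))) {
    p <- pmin(1, pi_other)
    p[pl$m[i]:(pl$m[i] + pl$l[i] - 1)] <- 1
    term <- 1
    for (n in seq_len(nrow(counts))) {
      q0 <- oracle_pb_zero(p[g[[n]]])
      term <- term * ((1 - q0) * oracle_dmn(counts[n, ], alpha1) +
                        q0 * oracle_dmn(counts[n, ], alpha0))
    }
    lik[i] <- term * w[pl$l[i]] / as.numeric(n_l[pl$l[i]])
  }
  pl$pp <- lik / sum(lik)
  pl
}

# Build a screen_data whose guides sit at the given target-site starts.
toy_screen <- function(starts, counts, chrom = "chrT", width = 10,
                       label = "targeting") {
  counts <- rbind(counts)
  screen_data(data.frame(guide_id = paste0("g", seq_along(starts)),
                         chrom = chrom, start = starts,
                         end = starts + width,
                         label = rep(label, length.out = length(starts)),
                         stringsAsFactors = FALSE),
              counts)
}

# Sample Dirichlet-multinomial counts: n rows, fixed total per row.
rdmn <- function(n, alpha, total) {
  t(vapply(seq_len(n), function(i) {
    g <- rgamma(length(alpha), alpha)
    as.integer(rmultinom(1, total, g / sum(g)))
  }, integer(length(alpha))))
}

# Screen with `n_bg` background guides far from a control region and
# `n_fs` guides inside it, with counts drawn from the two DMN components.
# Returns list(data, segmap, pi0).
recovery_screen <- function(n_bg = 2000, n_fs = 200, alpha0 = c(5, 5),
                            alpha1 = c(2, 8), total = 100) {
  fs_starts <- seq(0, by = 20, length.out = n_fs)
  bg_starts <- seq(50000, by = 20, length.out = n_bg)
  counts <- rbind(rdmn(n_fs, alpha1, total), rdmn(n_bg, alpha0, total))
  data <- toy_screen(c(fs_starts, bg_starts), counts)
  segmap <- build_segment_map(data, segment_size = 100, effect_range = 0)
  ctrl <- data.frame(chrom = "chrT", start = 0,
                     end = max(fs_starts) + 10)
  pi0 <- mark_fs0(segmap, ctrl)
  list(data = data, segmap = segmap, pi0 = pi0)
}

# Write a small CSV screen file for I/O tests.
write_toy_csv <- function(path, rows) {
  writeLines(rows, path)
  path
}
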