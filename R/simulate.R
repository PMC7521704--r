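#' Simulation configuration
#'
#' Describes a synthetic tiling CRISPR screen: the screened region, the
#' sgRNA library, the true functional sequences, and the experimental steps
#' (infection, sorting, sequencing). The generative pipeline is: per-guide
#' library counts ~ zero-inflated negative binomial; an input cell pool by
#' multinomial sampling from the library; sorting of each guide's cells
#' into pools by a Dirichlet-multinomial whose shapes are `alpha` for cells
#' with ineffective guides or guides outside functional sequences, and
#' `alpha + h_k * T` for the `w = round(c * f_n)` effective cells of guides
#' overlapping functional sequence k; and sequencing by multivariate
#' hypergeometric (without replacement, emulating UMI deduplication) or
#' multinomial (with replacement) draws.
#'
#' @param screen_type `"expression"` (FACS bins + a sequenced input pool) or
#'   `"selection"` (before/after pools per replicate).
#' @param perturbation `"CRISPRi"`, `"CRISPRa"` or `"Cas9"` (sets the default
#'   simulation area of effect; `"dual"` is declared but not supported).
#' @param region_length,n_guides screened span (bp) and number of evenly
#'   tiled sgRNAs.
#' @param n_fs,fs_length number and width (bp) of true functional sequences.
#' @param fs0_length width of the central positive-control element (h = 1).
#' @param effect_range simulation area of effect added on each side of a
#'   target site; default 500 (CRISPRi/CRISPRa) or 20 (Cas9).
#' @param min_gap minimum gap between placed elements; default
#'   `2 * effect_range` so neighbouring signals stay resolvable.
#' @param bin_names FACS bin labels for expression screens (default low,
#'   medium, high; the phenotype-relevant bin is the last).
#' @param alpha background Dirichlet sorting shapes (default symmetric 10).
#' @param T_strength selection-strength vector (Dirichlet mass added for
#'   effective functional guides); default puts 10 on the last bin.
#' @param eff_beta,strength_beta Beta shapes for guide efficiency f_n and
#'   element strength h_k.
#' @param zinb named vector `c(mu, d, eps)` of library count parameters.
#' @param n_cells cells in the input pool (default `2000 * n_guides`).
#' @param depth sequencing reads per guide per pool (default 400).
#' @param sampling `"without_replacement"` or `"with_replacement"`.
#' @param n_replicates replicate sorts of the input pool.
#' @param seed integer seed; if non-NULL, [simulate_screen()] seeds the RNG.
#'
#' @return An object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(screen_type = c("expression", "selection"),
                       perturbation = c("CRISPRi", "CRISPRa", "Cas9", "dual"),
                       region_length = 150000, n_guides = 8700,
                       n_fs = 8, fs_length = 50, fs0_length = 500,
                       effect_range = NULL, min_gap = NULL,
                       bin_names = c("low", "medium", "high"),
                       alpha = NULL, T_strength = NULL,
                       eff_beta = c(5, 2), strength_beta = c(8, 2),
                       zinb = c(mu = 300, d = 2, eps = 0.05),
                       n_cells = NULL, depth = 400,
                       sampling = c("without_replacement",
                                    "with_replacement"),
                       n_replicates = 1, seed = NULL) {
  screen_type <- match.arg(screen_type)
  perturbation <- match.arg(perturbation)
  if (perturbation == "dual")
    stop_tilefs("dual-guide simulation is not supported",
                class = "tilefs_not_supported")
  sampling <- match.arg(sampling)
  if (is.null(effect_range))
    effect_range <- if (perturbation == "Cas9") 20 else 500
  if (is.null(min_gap)) min_gap <- 2 * effect_range
  n_bins <- if (screen_type == "expression") length(bin_names) else 2L
  if (is.null(alpha)) alpha <- rep(10, n_bins)
  if (is.null(T_strength)) {
    T_strength <- rep(0, n_bins)
    T_strength[n_bins] <- 10
  }
  if (length(alpha) != n_bins || length(T_strength) != n_bins)
    stop_tilefs("alpha and T_strength must have one entry per sorted pool (",
                n_bins, ")", class = "tilefs_config_error")
  if (is.null(n_cells)) n_cells <- 2000 * n_guides
  stopifnot(region_length >= 1, n_guides >= 2, n_fs >= 0, fs_length >= 1,
            all(alpha > 0), all(T_strength >= 0),
            all(eff_beta > 0), all(strength_beta > 0),
            zinb[["mu"]] > 0, zinb[["d"]] > 0,
            zinb[["eps"]] >= 0, zinb[["eps"]] < 1,
            n_cells >= 1, depth >= 1, n_replicates >= 1)
  structure(list(screen_type = screen_type, perturbation = perturbation,
                 region_length = as.integer(region_length),
                 n_guides = as.integer(n_guides), n_fs = as.integer(n_fs),
                 fs_length = as.integer(fs_length),
                 fs0_length = as.integer(fs0_length),
                 effect_range = as.integer(effect_range),
                 min_gap = as.integer(min_gap),
                 bin_names = if (screen_type == "expression") bin_names
                             else c("before", "after"),
                 alpha = alpha, T_strength = T_strength,
                 eff_beta = eff_beta, strength_beta = strength_beta,
                 zinb = zinb, n_cells = n_cells, depth = depth,
                 sampling = sampling,
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "sim_config")
}

#' Preset simulation configurations
#'
#' Named scenario presets: `"facs"` is a 4-pool gene-expression screen
#' (input + 3 FACS bins, 8,700 guides tiling 150 kb with eight 50 bp
#' functional sequences); `"proliferation"` is the matching 2-pool
#' selection screen; `"facs_small"` is the expression scenario scaled to a
#' 30 kb region with ~1,700 guides; `"null_small"` is `facs_small` with the
#' selection strength zeroed (no functional signal). Depth, sgRNA
#' efficiency and selection strength follow the standard condition grid
#' (see [sim_preset_grid()]).
#'
#' @param name preset name.
#' @param depth `"high"` (400 reads/guide/pool) or `"medium"` (100).
#' @param efficiency guide-efficiency distribution: `"high"` Beta(5,2),
#'   `"medium"` Beta(5,5), `"low"` Beta(2,5).
#' @param selection selection strength: `"strong"` adds Dirichlet mass 10
#'   to the phenotype pool, `"weak"` adds 2.
#' @param ... overrides passed to [sim_config()].
#' @return A [sim_config].
#' @export
sim_preset <- function(name = c("facs", "proliferation", "facs_small",
                                "null_small"),
                       depth = c("high", "medium"),
                       efficiency = c("high", "medium", "low"),
                       selection = c("strong", "weak"), ...) {
  name <- match.arg(name)
  depth <- c(high = 400, medium = 100)[[match.arg(depth)]]
  eff_beta <- switch(match.arg(efficiency),
                     high = c(5, 2), medium = c(5, 5), low = c(2, 5))
  t_mass <- c(strong = 10, weak = 2)[[match.arg(selection)]]
  base <- switch(name,
    facs = list(screen_type = "expression"),
    proliferation = list(screen_type = "selection"),
    facs_small = list(screen_type = "expression", region_length = 30000,
                      n_guides = 1700),
    null_small = list(screen_type = "expression", region_length = 30000,
                      n_guides = 1700))
  n_bins <- if (base$screen_type == "expression") 3L else 2L
  T_strength <- rep(0, n_bins)
  T_strength[n_bins] <- if (name == "null_small") 0 else t_mass
  # explicit overrides in ... take precedence over the preset values
  args <- c(list(...), base, list(depth = depth, eff_beta = eff_beta,
                                  T_strength = T_strength))
  do.call(sim_config, args[!duplicated(names(args))])
}

#' @describeIn sim_preset The full condition grid: 2 scenarios x 2 depths x
#'   3 efficiency distributions x 2 selection strengths (24 rows).
#' @export
sim_preset_grid <- function() {
  expand.grid(name = c("facs", "proliferation"),
              depth = c("medium", "high"),
              efficiency = c("low", "medium", "high"),
              selection = c("weak", "strong"),
              stringsAsFactors = FALSE)
}

#' Sample sgRNA library counts
#'
#' Zero-inflated negative binomial library representation: each count is 0
#' with probability `eps`, otherwise NB with mean `mu` and dispersion `d`
#' (variance `mu + mu^2 / d`).
#'
#' @param n number of guides.
#' @param mu,d,eps ZINB parameters.
#' @return Integer vector of library counts.
#' @export
sample_library <- function(n, mu, d, eps = 0) {
  stopifnot(mu > 0, d > 0, eps >= 0, eps < 1)
  y <- rnbinom(n, mu = mu, size = d)
  zero <- runif(n) < eps
  y[zero] <- 0L
  y
}

#' Fit ZINB parameters to observed library counts
#'
#' Maximum-likelihood estimation of the zero-inflated negative binomial
#' parameters (mu, d, eps) from a table of sgRNA counts, by L-BFGS-B over
#' (log mu, log d, eps).
#'
#' @param counts non-negative integer vector (>= 50 values recommended).
#' @return Named numeric vector `c(mu, d, eps)` with attribute `"loglik"`.
#' @export
fit_zinb <- function(counts) {
  if (!is_count_vector(counts))
    stop_tilefs("counts must be non-negative integers",
                class = "tilefs_domain_error")
  if (all(counts == 0))
    stop_tilefs("all counts are zero; ZINB parameters are not identifiable",
                class = "tilefs_domain_error")
  y <- as.numeric(counts)
  nz <- y > 0
  negll <- function(par) {
    mu <- exp(par[1]); d <- exp(par[2]); eps <- par[3]
    ll0 <- log(eps + (1 - eps) * dnbinom(0, mu = mu, size = d))
    llp <- log1p(-eps) + dnbinom(y[nz], mu = mu, size = d, log = TRUE)
    -(sum(!nz) * ll0 + sum(llp))
  }
  zf <- mean(!nz)
  mu0 <- mean(y[nz])
  v <- stats::var(y[nz])
  d0 <- if (is.finite(v) && v > mu0) mu0^2 / (v - mu0) else 10
  par0 <- c(log(mu0), log(max(d0, 1e-2)), max(zf / 2, 1e-4))
  opt <- optim(par0, negll, method = "L-BFGS-B",
               lower = c(log(1e-3), log(1e-4), 0),
               upper = c(log(1e9), log(1e6), 1 - 1e-9))
  out <- c(mu = exp(opt$par[1]), d = exp(opt$par[2]), eps = opt$par[3])
  attr(out, "loglik") <- -opt$value
  out
}

#' Place the true functional sequences
#'
#' Draws `n_fs` non-overlapping functional-sequence intervals uniformly at
#' random, keeping at least `min_gap` bp between elements (and from the
#' positive-control element, which is placed centrally with strength
#' h = 1). Element strengths h_k ~ Beta(`strength_beta`) and per-guide
#' efficiencies f_n ~ Beta(`eff_beta`).
#'
#' @param config a [sim_config].
#' @return An object of class `"sim_truth"`: list with `fs` (data.frame
#'   `chrom`,`start`,`end`,`h`), `fs0` (one-row data.frame, h = 1), and
#'   `efficiency` (f_n per guide).
#' @export
place_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  len <- config$region_length
  w <- config$fs_length
  gap <- config$min_gap
  fs0_start <- as.integer(round(len / 2 - config$fs0_length / 2))
  fs0 <- data.frame(chrom = "chrS", start = fs0_start,
                    end = fs0_start + config$fs0_length, h = 1)
  spans <- rbind(c(0, fs0$start - gap), c(fs0$end + gap, len))
  spans <- spans[spans[, 2] - spans[, 1] >= w, , drop = FALSE]
  n <- config$n_fs
  starts <- integer(0)
  if (n > 0) {
    # capacity of a span for k elements of width w with min_gap between them
    cap <- function(L, k) L - k * w - (k - 1) * gap
    for (try in seq_len(1000)) {
      n_left <- rbinom(1, n, (spans[1, 2] - spans[1, 1]) /
                              sum(spans[, 2] - spans[, 1]))
      ks <- c(n_left, n - n_left)[seq_len(nrow(spans))]
      if (nrow(spans) == 1) ks <- n
      if (all(vapply(seq_len(nrow(spans)), function(i)
            ks[i] == 0 || cap(spans[i, 2] - spans[i, 1], ks[i]) >= 0,
            logical(1))) && sum(ks) == n) {
        starts <- unlist(lapply(seq_len(nrow(spans)), function(i) {
          k <- ks[i]
          if (k == 0) return(integer(0))
          slack <- cap(spans[i, 2] - spans[i, 1], k)
          u <- sort(runif(k, 0, slack))
          as.integer(round(spans[i, 1] + u + (seq_len(k) - 1) * (w + gap)))
        }))
        break
      }
    }
    if (length(starts) != n)
      stop_tilefs("cannot pack ", n, " functional sequences of ", w,
                  " bp with gap ", gap, " into ", len, " bp",
                  class = "tilefs_config_error")
  }
  fs <- data.frame(chrom = rep("chrS", n), start = starts,
                   end = starts + w,
                   h = rbeta(n, config$strength_beta[1],
                             config$strength_beta[2]))
  fs <- fs[order(fs$start), , drop = FALSE]
  rownames(fs) <- NULL
  structure(list(fs = fs, fs0 = fs0,
                 efficiency = rbeta(config$n_guides, config$eff_beta[1],
                                    config$eff_beta[2])),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulated truth:", nrow(x$fs), "functional sequence(s) plus the",
      "positive control\n")
  print(rbind(cbind(x$fs0, role = "FS0"),
              cbind(x$fs, role = paste0("FS", seq_len(nrow(x$fs))))),
        row.names = FALSE)
  invisible(x)
}

# Element strength per guide: max h over elements whose simulation-scale
# effect window overlaps the guide's target site (FS0 counts with h = 1);
# 0 for guides overlapping nothing.
guide_strengths <- function(guides, truth, effect_range) {
  els <- rbind(truth$fs0[c("start", "end", "h")],
               truth$fs[c("start", "end", "h")])
  h <- numeric(nrow(guides))
  lo <- guides$start - effect_range
  hi <- guides$end + effect_range
  for (i in seq_len(nrow(els))) {
    hit <- lo < els$end[i] & hi > els$start[i]
    h[hit] <- pmax(h[hit], els$h[i])
  }
  h
}

# One Dirichlet-multinomial draw of `size` items over length(alpha) bins.
rdirmult <- function(size, alpha) {
  if (size == 0) return(integer(length(alpha)))
  g <- rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  as.integer(rmultinom(1, size, g / sum(g)))
}

#' Sort cells into pools
#'
#' For each guide, `w = round(c_n * f_n)` cells carry an effective guide and
#' are sorted by a Dirichlet-multinomial draw with shapes
#' `alpha + h_n * T`; the remaining cells (and all cells of guides that
#' overlap no functional sequence, h = 0) sort with shapes `alpha`. Pool
#' counts per guide always sum to the input cell count.
#'
#' @param cells integer vector of input-pool cells per guide.
#' @param h per-guide element strength in \[0, 1\] (0 = no overlap).
#' @param f per-guide efficiency in \[0, 1\].
#' @param alpha background Dirichlet shapes (length = number of pools).
#' @param T_strength selection-strength vector (same length).
#' @return Integer matrix, guides x pools.
#' @export
sort_cells <- function(cells, h, f, alpha, T_strength) {
  stopifnot(length(cells) == length(h), length(h) == length(f),
            all(cells >= 0), all(h >= 0 & h <= 1), all(f >= 0 & f <= 1),
            length(alpha) == length(T_strength))
  n <- length(cells)
  out <- matrix(0L, n, length(alpha))
  for (i in seq_len(n)) {
    if (h[i] > 0) {
      w <- round(cells[i] * f[i])
      out[i, ] <- rdirmult(w, alpha + h[i] * T_strength) +
        rdirmult(cells[i] - w, alpha)
    } else {
      out[i, ] <- rdirmult(cells[i], alpha)
    }
  }
  out
}

# Multivariate hypergeometric draw: k items from urns with x[i] items each.
rmvhyper <- function(x, k) {
  out <- integer(length(x))
  rest <- sum(x)
  for (i in seq_along(x)) {
    rest <- rest - x[i]
    out[i] <- rhyper(1, x[i], rest, k)
    k <- k - out[i]
  }
  out
}

#' Sequence the sorted pools
#'
#' Draws `depth * n_guides` reads per pool across guides, either without
#' replacement (multivariate hypergeometric; models UMI-deduplicated reads
#' and requires the read budget not to exceed the pool's cell count) or
#' with replacement (multinomial).
#'
#' @param cells integer matrix, guides x pools, of sorted cell counts.
#' @param depth reads per guide per pool.
#' @param sampling `"without_replacement"` or `"with_replacement"`.
#' @return Integer matrix of observed counts, same shape as `cells`.
#' @export
sequence_pools <- function(cells, depth,
                           sampling = c("without_replacement",
                                        "with_replacement")) {
  sampling <- match.arg(sampling)
  cells <- as.matrix(cells)
  reads <- as.integer(round(depth * nrow(cells)))
  out <- matrix(0L, nrow(cells), ncol(cells))
  for (j in seq_len(ncol(cells))) {
    total <- sum(cells[, j])
    if (sampling == "without_replacement") {
      if (reads > total)
        stop_tilefs("read budget (", reads, ") exceeds pool ", j,
                    " cell count (", total, "); use sampling = ",
                    "\"with_replacement\"", class = "tilefs_config_error")
      out[, j] <- if (reads == total) cells[, j] else rmvhyper(cells[, j],
                                                               reads)
    } else {
      if (total == 0)
        stop_tilefs("pool ", j, " has no cells to sequence",
                    class = "tilefs_config_error")
      out[, j] <- as.integer(rmultinom(1, reads, cells[, j] / total))
    }
  }
  dimnames(out) <- dimnames(cells)
  out
}

#' Simulate a complete tiling CRISPR screen
#'
#' Runs the full generative pipeline (library, input pool, per-replicate
#' sorting, sequencing) and returns the observed counts in the analysis
#' input format together with the simulated ground truth. Guide target
#' sites are evenly tiled across the region; guides whose target site
#' overlaps the positive-control element are labelled
#' `"positive_control"`. Expression screens emit one shared `input` column
#' (sequenced from the pre-sort pool) plus one column per FACS bin and
#' replicate; selection screens emit `before`/`after` columns per
#' replicate.
#'
#' @param config a [sim_config]; `config$seed`, when non-NULL, seeds the
#'   RNG so the output is fully reproducible.
#' @return List with `data` (a [screen_data]), `truth` (a [place_truth]
#'   result), and `config`.
#' @export
simulate_screen <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_guides
  site_w <- 20L
  starts <- as.integer(round((seq_len(n) - 1) *
                             (config$region_length - site_w) / (n - 1)))
  guides <- data.frame(guide_id = sprintf("guide_%05d", seq_len(n)),
                       chrom = "chrS", start = starts,
                       end = starts + site_w, label = "targeting",
                       stringsAsFactors = FALSE)
  truth <- place_truth(config)
  guides$label[guides$start < truth$fs0$end &
               guides$end > truth$fs0$start] <- "positive_control"
  lib <- sample_library(n, config$zinb[["mu"]], config$zinb[["d"]],
                        config$zinb[["eps"]])
  if (sum(lib) == 0)
    stop_tilefs("simulated library is empty", class = "tilefs_config_error")
  cells <- as.integer(rmultinom(1, config$n_cells, lib / sum(lib)))
  h <- guide_strengths(guides, truth, config$effect_range)
  cols <- list()
  pool_names <- character(0)
  replicate_of <- character(0)
  if (config$screen_type == "expression") {
    cols$input <- sequence_pools(matrix(cells, ncol = 1), config$depth,
                                 config$sampling)[, 1]
    pool_names <- "input"
    replicate_of <- c(input = "shared")
  }
  for (r in seq_len(config$n_replicates)) {
    sorted <- sort_cells(cells, h, truth$efficiency, config$alpha,
                         config$T_strength)
    if (config$screen_type == "selection") {
      seqd <- cbind(sequence_pools(matrix(cells, ncol = 1), config$depth,
                                   config$sampling)[, 1],
                    sequence_pools(sorted[, 2, drop = FALSE], config$depth,
                                   config$sampling)[, 1])
      nm <- paste0("rep", r, "_", c("before", "after"))
    } else {
      seqd <- sequence_pools(sorted, config$depth, config$sampling)
      nm <- paste0("rep", r, "_", config$bin_names)
    }
    for (j in seq_len(ncol(seqd))) cols[[nm[j]]] <- seqd[, j]
    pool_names <- c(pool_names, nm)
    replicate_of <- c(replicate_of, setNames(rep(paste0("rep", r),
                                                 length(nm)), nm))
  }
  counts <- do.call(cbind, cols)
  colnames(counts) <- pool_names
  list(data = screen_data(guides, counts, pool_names, replicate_of),
       truth = truth, config = config)
}
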