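test_that("length prior follows the truncated geometric form", {
  lp <- length_prior(0.5, 2)
  expect_equal(lp$w, c(2 / 3, 1 / 3))
  expect_equal(length_prior(0.37, 1)$w, 1)
  lp10 <- length_prior(0.1, 10)
  direct <- 0.9^(0:9) * 0.1 / sum(0.9^(0:9) * 0.1)
  expect_equal(lp10$w, direct, tolerance = 1e-12)
  expect_equal(sum(lp10$w), 1, tolerance = 1e-12)
  expect_true(all(diff(lp10$w) < 0))
  expect_error(length_prior(0), class = "tilefs_domain_error")
  expect_error(length_prior(1), class = "tilefs_domain_error")
})

test_that("combined segment probability adds placements and clips", {
  pi <- matrix(0, 2, 10)
  p <- segment_probability(pi, placement = list(m = 5, l = 2))
  expect_equal(which(p == 1), c(5, 6))
  expect_true(all(p[-c(5, 6)] == 0))

  pi0 <- matrix(0, 1, 12)
  pi0[1, 10] <- 1
  expect_equal(segment_probability(pi0)[10], 1)

  two <- matrix(0, 2, 5)
  two[, 3] <- 0.6
  expect_equal(segment_probability(two)[3], 1)
})

test_that("placement posteriors normalise and reduce to the prior", {
  # 3 segments, L = 2 -> 3 + 2 = 5 placements
  d <- toy_screen(c(0, 150, 290), rdmn(3, c(5, 5), 60))
  sm <- build_segment_map(d, segment_size = 100, effect_range = 0)
  expect_equal(sm$M, 3)
  model <- sorting_model(c(5, 5), c(2, 8))
  prior <- length_prior(0.3, 2)
  pp <- placement_posteriors(d, sm, matrix(0, 2, 3), model, prior)
  expect_equal(nrow(pp), 5)
  expect_equal(sum(pp$pp), 1, tolerance = 1e-9)

  # identical components: the posterior is the prior
  same <- sorting_model(c(5, 5), c(5, 5))
  pp2 <- placement_posteriors(d, sm, matrix(0, 2, 3), same, prior)
  expect_equal(pp2$pp, exp(pp2$log_prior) / sum(exp(pp2$log_prior)),
               tolerance = 1e-12)
})

test_that("a lone informative guide pins the placement posterior", {
  set.seed(3)
  starts <- c(0, 610, 1990)
  counts <- rbind(c(0L, 0L), c(0L, 50L), c(0L, 0L))
  d <- toy_screen(starts, counts)
  sm <- build_segment_map(d, segment_size = 100, effect_range = 0)
  expect_equal(sm$M, 20)
  expect_equal(sm$g[[2]], 7)
  model <- sorting_model(c(9, 1), c(1, 9))
  pp <- placement_posteriors(d, sm, matrix(0, 2, 20), model,
                             length_prior(0.1, 10))
  l1 <- pp[pp$l == 1, ]
  expect_equal(l1$m[which.max(l1$pp)], 7)
})

test_that("incremental likelihood evaluation equals the naive product", {
  set.seed(19)
  starts <- sort(sample(0:3000, 40))
  d <- toy_screen(starts, rdmn(40, c(4, 6, 2), 50), width = 15)
  sm <- build_segment_map(d, segment_size = 100, effect_range = 150)
  pi <- rbind(as.numeric(seq_len(sm$M) %in% 2:3),
              runif(sm$M) * 0.4)
  model <- sorting_model(c(4, 6, 2), c(1, 2, 9))
  prior <- length_prior(0.2, 5)
  inc <- placement_posteriors(d, sm, pi, model, prior)
  nai <- placement_posteriors(d, sm, pi, model, prior, method = "naive")
  expect_equal(inc$log_lik, nai$log_lik, tolerance = 1e-8)
  expect_equal(inc$pp, nai$pp, tolerance = 1e-8)
})

test_that("segment projection of the posterior matches hand summation", {
  conc <- data.frame(m = 4, l = 2, pp = 1.0)
  expect_equal(update_pi_row(conc, 8),
               c(0, 0, 0, 1, 1, 0, 0, 0))
  unif <- data.frame(m = c(1, 2, 3, 1, 2), l = c(1, 1, 1, 2, 2),
                     pp = rep(0.2, 5))
  expect_equal(update_pi_row(unif, 3), c(0.4, 0.6, 0.4))
  expect_equal(sum(update_pi_row(unif, 3)), sum(unif$pp * unif$l))
})

test_that("one stepwise sweep equals the exact single-sequence posterior", {
  set.seed(23)
  # M = 8 tiny instance, 12 guides, L = 2
  starts <- c(5, 120, 210, 290, 350, 410, 455, 520, 610, 650, 720, 780)
  counts <- rdmn(12, c(5, 5), 40)
  counts[5:7, ] <- rdmn(3, c(1, 9), 40) # signal near segments 4-5
  d <- toy_screen(starts, counts)
  sm <- build_segment_map(d, segment_size = 100, effect_range = 0)
  expect_equal(sm$M, 8)
  pi0 <- c(1, rep(0, 7))
  model <- sorting_model(c(5, 5), c(2, 8))
  prior <- length_prior(0.3, 2)
  fit <- ibss_fit(d, sm, pi0, K = 1, prior = prior, tol = Inf,
                  model = model, refit_model = FALSE, exclude_fs0 = FALSE)
  expect_equal(fit$n_iter, 1)
  oracle <- oracle_placement_posterior(d$counts, sm$g, pi0,
                                       model$alpha0, model$alpha1,
                                       prior$w)
  cover <- numeric(8)
  for (i in seq_len(nrow(oracle)))
    cover[oracle$m[i]:(oracle$m[i] + oracle$l[i] - 1)] <-
      cover[oracle$m[i]:(oracle$m[i] + oracle$l[i] - 1)] + oracle$pp[i]
  expect_equal(unname(fit$pi[2, ]), cover, tolerance = 1e-10)
  # row mass is the posterior expected length
  expect_equal(sum(fit$pi[2, ]), sum(oracle$pp * oracle$l),
               tolerance = 1e-10)
  expect_gte(sum(fit$pi[2, ]), 1 - 1e-9)
  expect_lte(sum(fit$pi[2, ]), prior$L + 1e-9)
})

test_that("the two-sequence fixed point tracks the exact pair posterior", {
  set.seed(29)
  starts <- c(5, 120, 210, 290, 350, 410, 455, 520, 610, 650, 720, 780)
  counts <- rdmn(12, c(5, 5), 40)
  counts[3:4, ] <- rdmn(2, c(1, 9), 40)  # signal at segment 3 area
  counts[9:10, ] <- rdmn(2, c(1, 9), 40) # signal at segments 6-7
  d <- toy_screen(starts, counts)
  sm <- build_segment_map(d, segment_size = 100, effect_range = 0)
  pi0 <- c(1, rep(0, 7))
  model <- sorting_model(c(5, 5), c(2, 8))
  prior <- length_prior(0.3, 2)
  fit <- ibss_fit(d, sm, pi0, K = 2, prior = prior, tol = 1e-8,
                  max_iter = 200, model = model, refit_model = FALSE,
                  exclude_fs0 = FALSE)
  # exact posterior over ordered placement pairs
  pl <- oracle_placements(8, 2)
  n_l <- table(factor(pl$l, levels = 1:2))
  lp <- log(prior$w[pl$l]) - log(as.numeric(n_l[pl$l]))
  post <- matrix(0, nrow(pl), nrow(pl))
  for (i in seq_len(nrow(pl))) for (j in seq_len(nrow(pl))) {
    p <- pmin(1, pi0 +
                as.numeric(seq_len(8) %in% pl$m[i]:(pl$m[i] + pl$l[i] - 1)) +
                as.numeric(seq_len(8) %in% pl$m[j]:(pl$m[j] + pl$l[j] - 1)))
    ll <- 0
    for (n in seq_len(nrow(counts)))
      ll <- ll + log((1 - oracle_pb_zero(p[sm$g[[n]]])) *
                       oracle_dmn(counts[n, ], model$alpha1) +
                     oracle_pb_zero(p[sm$g[[n]]]) *
                       oracle_dmn(counts[n, ], model$alpha0))
    post[i, j] <- lp[i] + lp[j] + ll
  }
  post <- exp(post - max(post))
  post <- post / sum(post)
  p_exact <- vapply(seq_len(8), function(m) {
    covered_i <- pl$m <= m & pl$m + pl$l - 1 >= m
    sum(post[covered_i, ]) + sum(post[, covered_i]) -
      sum(post[covered_i, covered_i])
  }, numeric(1))
  p_ibss <- pmin(1, colSums(fit$pi[-1, , drop = FALSE]))
  free <- 2:8 # segment 1 is the positive control
  top_exact <- free[order(p_exact[free], decreasing = TRUE)][1:2]
  top_ibss <- free[order(p_ibss[free], decreasing = TRUE)][1:2]
  expect_setequal(top_exact, top_ibss)
  tv <- 0.5 * sum(abs(p_exact[free] / sum(p_exact[free]) -
                        p_ibss[free] / sum(p_ibss[free])))
  cat("\n  [info] TV distance, exact vs stepwise 2-FS marginal:",
      signif(tv, 3), "\n")
})

test_that("a planted element is recovered; null data carry little evidence", {
  cfg <- sim_config(screen_type = "expression", region_length = 10000,
                    n_guides = 600, n_fs = 1, effect_range = 200,
                    strength_beta = c(1e6, 1), eff_beta = c(50, 1),
                    seed = 31)
  sim <- simulate_screen(cfg)
  sm <- build_segment_map(sim$data, 100, 200)
  pi0 <- mark_fs0(sm, sim$truth$fs0)
  fit <- ibss_fit(sim$data, sm, pi0, K = 1)
  top <- sm$segments[which.max(fit$pi[2, ]), ]
  expect_equal(as.character(top$chrom), "chrS")
  expect_lt(top$start, sim$truth$fs$end)
  expect_gt(top$end, sim$truth$fs$start)

  # With no signal the algorithm still places a sequence (it must), but
  # the data support for that placement -- the log-likelihood gained over
  # the controls-only initialisation -- is orders of magnitude smaller
  # than for a planted element.
  null_cfg <- sim_config(screen_type = "expression", region_length = 10000,
                         n_guides = 600, n_fs = 0,
                         T_strength = c(0, 0, 0), seed = 32)
  null_sim <- simulate_screen(null_cfg)
  sm0 <- build_segment_map(null_sim$data, 100, 200)
  pi00 <- mark_fs0(sm0, null_sim$truth$fs0)
  fit0 <- suppressWarnings(ibss_fit(null_sim$data, sm0, pi00, K = 1))
  gain_planted <- max(fit$loglik_trace) - fit$loglik_trace[1]
  gain_null <- max(fit0$loglik_trace) - fit0$loglik_trace[1]
  expect_gt(gain_planted, 20)
  expect_lt(gain_null, gain_planted / 3)
})

test_that("convergence control and determinism behave as contracted", {
  set.seed(37)
  d <- toy_screen(seq(0, 1900, by = 100), rdmn(20, c(5, 5), 50))
  sm <- build_segment_map(d, 100, 0)
  pi0 <- as.numeric(seq_len(sm$M) %in% 1:2)
  model <- sorting_model(c(5, 5), c(2, 8))
  fit1 <- ibss_fit(d, sm, pi0, K = 1, tol = Inf, model = model,
                   refit_model = FALSE)
  expect_equal(fit1$n_iter, 1)
  fit2 <- ibss_fit(d, sm, pi0, K = 1, tol = Inf, model = model,
                   refit_model = FALSE)
  expect_identical(fit1$pi, fit2$pi)
  expect_identical(fit1$loglik_trace, fit2$loglik_trace)
})

test_that("the correlation criterion selects the planted number of elements", {
  cfg <- sim_config(screen_type = "expression", region_length = 12000,
                    n_guides = 700, n_fs = 2, effect_range = 200,
                    strength_beta = c(1e6, 1), eff_beta = c(50, 1),
                    seed = 41)
  sim <- simulate_screen(cfg)
  sm <- build_segment_map(sim$data, 100, 200)
  pi0 <- mark_fs0(sm, data.frame(chrom = "chrS",
                                 start = sim$truth$fs0$start - 400,
                                 end = sim$truth$fs0$end + 400))
  sel <- select_k(sim$data, sm, pi0, k_max = 4)
  expect_equal(sel$K, 2)
  expect_equal(sel$diagnostics$max_corr[1], -Inf)
  pr <- precision_recall(credible_regions(sel$fit), sim$truth$fs)
  expect_equal(pr$recall_count, 2L)

  # an unreachable threshold runs to k_max
  sel2 <- suppressWarnings(select_k(sim$data, sm, pi0, k_max = 2,
                                    corr_threshold = 1.01))
  expect_equal(sel2$K, 2)
  expect_warning(select_k(sim$data, sm, pi0, k_max = 1,
                          corr_threshold = 1.01), "k_max")
})

test_that("credible regions accumulate, merge and honour coverage", {
  segs <- data.frame(chrom = "chrT", start = seq(0, 900, 100),
                     end = seq(100, 1000, 100))
  sm <- structure(list(segments = segs, M = 10, run = rep(1L, 10),
                       segment_size = 100L, effect_range = 0L),
                  class = "segment_map")
  mk_fit <- function(pp) structure(list(pp = list(pp), segmap = sm),
                                   class = "ibss_fit")
  # one dominant placement
  pp <- data.frame(m = c(3, 7, 9), l = c(3, 1, 1),
                   pp = c(0.96, 0.03, 0.01))
  r <- credible_regions(mk_fit(pp), 0.95)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(200, 500))
  # two adjacent half placements merge into one region
  pp2 <- data.frame(m = c(4, 5), l = c(1, 1), pp = c(0.5, 0.5))
  r2 <- credible_regions(mk_fit(pp2), 0.95)
  expect_equal(nrow(r2), 1)
  expect_equal(c(r2$start, r2$end), c(300, 500))
  expect_equal(r2$posterior, 1.0)
  # a gap yields two regions for the same sequence
  pp3 <- data.frame(m = c(2, 8), l = c(1, 1), pp = c(0.5, 0.5))
  r3 <- credible_regions(mk_fit(pp3), 0.95)
  expect_equal(nrow(r3), 2)
  # full coverage takes every supported placement
  pp4 <- data.frame(m = c(1, 5, 9), l = c(1, 1, 1),
                    pp = c(0.9, 0.1, 0))
  r4 <- credible_regions(mk_fit(pp4), 1.0)
  expect_equal(nrow(r4), 2)
})

test_that("the configuration count is exactly the binomial coefficient", {
  expect_equal(n_configurations(10, 2), choose(10, 2))
  expect_equal(n_configurations(6, 6), 1)
})
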