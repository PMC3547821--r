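# Smoke-level checks of the experiment drivers on small runs; the
# full-scale scientific claims are exercised in test-acceptance.R.

cfg_tiny <- evolution_config(N = 80, G = 40, replicates = 6, seed = 17)

test_that("the environment scan returns one labelled record per value", {
  sc <- suppressWarnings(
    scan_environment("HRM", cfg_tiny, b_values = c(10, 25) / 80))
  expect_s3_class(sc, "scan_result")
  expect_length(sc$records, 2)
  expect_true(all(scan_labels(sc) %in%
                    c("kink", "slowdown", "plateau", "decrease", "u_shape")))
  expect_lt(sc$records[[2]]$mean_x, sc$records[[1]]$mean_x)
  expect_error(scan_environment("HRM", cfg_tiny, b_values = c(0.2, 0.1)),
               class = "evohet_config_error")
})

test_that("the deterministic scan runs through the same driver", {
  cfg <- evolution_config(N = 100, G = 40, replicates = 2, seed = 1)
  sc <- scan_environment("HRM", cfg, b_values = c(10, 25) / 100,
                         method = "deterministic")
  expect_length(sc$records, 2)
  expect_lt(sc$records[[2]]$mean_x, sc$records[[1]]$mean_x)
})

test_that("stress response is the identity at the evolved b and labels all
          cells", {
  st <- find_stationary(hazard_params("HRM", a = 1e-3, b = 0.1),
                        mutation_kernel(0.01), nbins = 100, T_fill = 100,
                        tol = 1e-6, max_iter = 200)
  hp0 <- hazard_params("HRM", a = 1e-3, b = 0.1)
  sr <- stress_response(st$dist, hp0, b_new_values = c(0.05, 0.1, 0.2))
  same <- which(sr$b_new_values == 0.1)
  expect_equal(sr$curves[[same]]$hazard, sr$baseline$hazard,
               tolerance = 1e-12)
  expect_length(sr$labels, 3)
  expect_true(is.finite(sr$sensitivity) && sr$sensitivity > 0)
})

test_that("heat shock separates heterogeneous from homogeneous cohorts", {
  hp0 <- hazard_params("HRM", a = 1e-3, b = 0.05)
  st <- find_stationary(hp0, mutation_kernel(0.01), nbins = 100,
                        T_fill = 200, tol = 1e-6, max_iter = 200)
  shock <- hazard_params("HRM", a = 1e-3, b = 0.25)
  het <- heat_shock_survival(st$dist, shock)
  expect_true(all(diff(het$curve$surv) <= 1e-12))
  expect_equal(het$curve$surv[1], 1)

  delta <- trait_distribution(c(rep(0, 49), 1, rep(0, 50)))
  hom <- heat_shock_survival(delta, shock)
  expect_false(hom$two_stage)
  expect_gt(het$ratio, hom$ratio)
})

test_that("heat-shock survival from resampled lifespans matches the
          mixture closed form", {
  set.seed(40)
  hp <- hazard_params("HRM", a = 1e-3, b = 0.1)
  mass <- c(rep(2, 30), rep(0.2, 70))
  dist <- trait_distribution(mass)
  x <- sample(dist$grid, 1e5, replace = TRUE, prob = dist$mass)
  d <- draw_death_time(hp, x)
  Spop <- function(t) vapply(t, function(ti)
    sum(dist$mass * survival_probability(hp, dist$grid, ti)), numeric(1))
  ks <- suppressWarnings(ks.test(d, function(t) 1 - Spop(pmax(t, 0))))
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("the mutation-rate scan reports its invariance metrics", {
  sc <- suppressWarnings(
    scan_mutation_rate("HRM", cfg_tiny, pm_values = c(0.01, 0.1),
                       b = 20 / 80))
  expect_length(sc$records, 2)
  expect_true(is.finite(sc$metrics$left_invariance))
  expect_length(sc$metrics$tail_to_uniform, 2)
  expect_length(sc$metrics$labels, 2)
})

test_that("the oldest-old analysis pairs curves and evaluates the medfly
          checklist on constructed data", {
  oo <- suppressWarnings(oldest_old_analysis(cfg_tiny))
  expect_s3_class(oo$curve_excluding, "mortality_curve")
  expect_s3_class(oo$curve_including, "mortality_curve")
  expect_gte(max(oo$curve_including$time), max(oo$curve_excluding$time))

  # constructed two-group mixture with a long-lived 5% subgroup shows all
  # five medfly features
  fx <- make_fixtures(2)
  cv <- estimate_mortality(fx$medfly_mix, bins = seq(0, 300, by = 5))
  cv <- cv[is.finite(cv$log_hazard) & cv$deaths >= 5, ]
  feats <- evohet:::medfly_features(cv, df = 12)
  expect_true(all(feats))
})

test_that("subpopulation truncation at x_max = 1 reproduces the input", {
  fin <- data.frame(x = runif(500), death_time = rexp(500, 0.01))
  expect_identical(truncate_trait_tail(fin, 1), fin)
})

test_that("the deterministic engine reproduces the ordered transition
          sequence and matches the stochastic stationary mean", {
  cfg <- evolution_config(N = 500, G = 400, replicates = 2, seed = 1)
  expected <- c("kink", "slowdown", "plateau", "decrease", "u_shape")
  for (fam in c("HRM", "HTM")) {
    sc <- scan_environment(fam, cfg, method = "deterministic")
    expect_identical(scan_labels(sc), expected)
  }

  # finite-population drift vanishes with N: at N = 2000 the ensemble mean
  # matches the fixed point closely
  N <- 2000
  cfg2 <- evolution_config(N = N, G = 400, pm = 0.01, replicates = 50,
                           seed = 9)
  hp <- hazard_params("HRM", a = default_a(N, "HRM"),
                      b = default_b(N, "HRM"))
  res <- suppressWarnings(run_evolution(cfg2, hp, hist_bins = 200))
  st <- find_stationary(hp, mutation_kernel(0.01), nbins = 200, T_fill = N,
                        dt = 0.2, tol = 1e-7, max_iter = 1000)
  mids <- (seq_len(200) - 0.5) / 200
  expect_lt(abs(sum(mids * res$ensemble_hist[401, ]) -
                  sum(st$dist$grid * st$dist$mass)), 0.01)
})
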