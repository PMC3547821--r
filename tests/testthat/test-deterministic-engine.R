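hp_det <- hazard_params("HRM", a = 1e-4, b = 0.04)  # mid-grid at N = 500
kern <- mutation_kernel(0.01)

test_that("within-generation state decays pointwise from the input", {
  d <- uniform_trait_distribution(100)
  expect_equal(within_generation_state(d, hp_det, 0), d$mass)
  n1 <- within_generation_state(d, hp_det, 50)
  n2 <- within_generation_state(d, hp_det, 150)
  expect_true(all(n1 <= d$mass))
  expect_true(all(n2 <= n1))
  # HTM delta at x = 0 never decays
  ht <- hazard_params("HTM", a = 0.01, b = 0.01)
  d0 <- trait_distribution(c(1, rep(0, 199)),
                           grid = seq(0, 1, length.out = 200))
  expect_equal(within_generation_state(d0, ht, 1e5), d0$mass)
})

test_that("the generation operator normalizes, resets under pm = 1 and
          fixes deltas under pm = 0", {
  d <- trait_distribution(runif(200) + 0.1)
  out <- apply_generation_operator(d, hp_det, kern, T_fill = 500)
  expect_equal(sum(out$mass), 1, tolerance = 1e-12)

  out1 <- apply_generation_operator(d, hp_det, mutation_kernel(1),
                                    T_fill = 500)
  expect_equal(out1$mass, rep(1 / 200, 200), tolerance = 1e-12)

  dd <- trait_distribution(c(rep(0, 99), 1, rep(0, 100)))
  out0 <- apply_generation_operator(dd, hp_det, mutation_kernel(0),
                                    T_fill = 500)
  expect_equal(out0$mass, dd$mass, tolerance = 1e-12)
})

test_that("operator output is invariant to input mass scaling", {
  m <- runif(200) + 0.05
  d1 <- trait_distribution(m)
  d2 <- trait_distribution(7.3 * m)
  o1 <- apply_generation_operator(d1, hp_det, kern, T_fill = 500)
  o2 <- apply_generation_operator(d2, hp_det, kern, T_fill = 500)
  expect_equal(o1$mass, o2$mass, tolerance = 1e-12)
})

test_that("halving the time step barely changes one generation", {
  d <- uniform_trait_distribution(200)
  o1 <- apply_generation_operator(d, hp_det, kern, T_fill = 500, dt = 0.1)
  o2 <- apply_generation_operator(d, hp_det, kern, T_fill = 500, dt = 0.05)
  expect_lt(sum(abs(o1$mass - o2$mass)), 1e-6)
})

test_that("the reflected-Gaussian kernel matrix is column-stochastic and
          bounded to [0, 1]", {
  g <- uniform_trait_distribution(50)$grid
  K <- evohet:::kernel_matrix(mutation_kernel(0.1, "gaussian", 0.3), g)
  expect_equal(colSums(K), rep(1, 50), tolerance = 1e-9)
  expect_true(all(K >= 0))
  # folding a wide Gaussian: mass near both edges, none lost
  Kw <- evohet:::kernel_matrix(mutation_kernel(0.1, "gaussian", 2), g)
  expect_equal(colSums(Kw), rep(1, 50), tolerance = 1e-9)
})

test_that("without mutation the stationary distribution collapses to a
          peak around one value", {
  hp <- hazard_params("HRM", a = 1e-4, b = 0.02)  # kink-regime environment
  st <- find_stationary(hp, mutation_kernel(0), nbins = 100,
                        T_fill = 500, tol = 1e-10, max_iter = 4000)
  peak <- which.max(st$dist$mass)
  win <- max(1, peak - 1):min(100, peak + 1)
  expect_gt(sum(st$dist$mass[win]), 0.99)
})

test_that("the fixed point is stable and the mean trait decreases with b", {
  st <- find_stationary(hp_det, kern, nbins = 100, T_fill = 500,
                        tol = 1e-8, max_iter = 3000)
  again <- apply_generation_operator(st$dist, hp_det, kern, T_fill = 500)
  # the iteration mixes slowly near the fixed point: one further step must
  # not move the distribution more than the final recorded step
  expect_lt(sum(abs(again$mass - st$dist$mass)),
            max(1e-6, 1.5 * st$final_distance))
  expect_lt(st$final_distance, 1e-4)

  means <- vapply(c(6, 16, 20, 35, 120) / 500, function(b) {
    s <- find_stationary(hazard_params("HRM", a = 1e-4, b = b), kern,
                         nbins = 100, T_fill = 500, tol = 1e-6,
                         max_iter = 300)
    sum(s$dist$grid * s$dist$mass)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("mixture mortality equals the individual hazard for a delta and
          is bounded by the support maximum", {
  dd <- trait_distribution(c(rep(0, 120), 1, rep(0, 79)))
  x0 <- dd$grid[121]
  tg <- seq(1, 400, by = 7)
  cv <- mortality_from_distribution(dd, hp_det, tg)
  expect_equal(cv$hazard, hazard(hp_det, x0, tg), tolerance = 1e-12)

  d <- trait_distribution(runif(200) + 0.1)
  cvm <- mortality_from_distribution(d, hp_det, tg)
  hmax <- vapply(tg, function(t) max(hazard(hp_det, d$grid, t)), numeric(1))
  expect_true(all(cvm$hazard <= hmax[seq_len(nrow(cvm))] + 1e-12))
})

test_that("a Gamma frailty mixture reproduces the logistic hazard closed
          form", {
  # HTM with multiplicative Gamma frailty (mean 1, variance s2) on an
  # unbounded grid: population hazard a e^{bt} / (1 + (a s2 / b)(e^{bt}-1))
  a <- 0.001; b <- 0.05; s2 <- 0.5
  z <- seq(1e-4, 12, length.out = 4000)           # frailty grid
  w <- stats::dgamma(z, shape = 1 / s2, scale = s2)
  w <- w / sum(w)
  tg <- seq(0, 150, by = 1)
  S <- exp(-outer(z, tg, function(zz, t) (a * zz / b) * expm1(b * t)))
  M <- outer(z, tg, function(zz, t) a * zz * exp(b * t))
  mu_pop <- as.vector(crossprod(w, M * S)) / as.vector(crossprod(w, S))
  closed <- a * exp(b * tg) / (1 + (a * s2 / b) * expm1(b * tg))
  expect_equal(mu_pop, closed, tolerance = 1e-3)

  # the same computation through mortality_from_distribution on [0, 1]:
  # rescale frailty into the unit interval via x = z / zmax, k = 1
  zmax <- 12
  ht <- hazard_params("HTM", a = a * zmax, b = b)
  xg <- z / zmax
  dist <- trait_distribution(w, grid = xg)
  cv <- mortality_from_distribution(dist, ht, tg[-1])
  expect_equal(cv$hazard, closed[-1], tolerance = 1e-3)
})
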