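# EM fitting: responsibilities, corrections, updates, initialization.

test_that("e_step special cases and separation", {
  comp <- bgg_component(100, 10, 2)
  # identical components: every row equals the weights
  mix <- bgg_mixture(list(comp, comp), c(0.3, 0.7))
  banks <- mixture_banks(mix, 1e4, 3)
  vals <- matrix(c(80, 100, 130), ncol = 1)
  r <- e_step(vals, mix, banks)
  expect_equal(r, matrix(rep(c(0.3, 0.7), each = 3), 3, 2), tolerance = 1e-12)
  expect_equal(rowSums(r), rep(1, 3), tolerance = 1e-12)
  # M = 1: all ones
  mix1 <- bgg_mixture(list(comp), 1)
  expect_equal(e_step(vals, mix1, mixture_banks(mix1, 1e4, 3)),
               matrix(1, 3, 1))
  # 10-sigma separation: near-hard assignment at a component mean
  mix2 <- bgg_mixture(list(bgg_component(60, 3, 2), bgg_component(90, 3, 2)),
                      c(0.5, 0.5))
  r2 <- e_step(matrix(60, 1, 1), mix2, mixture_banks(mix2, 1e4, 3))
  expect_gt(r2[1, 1], 0.999)
})

test_that("mean_correction: symmetry cancellation and sign under asymmetry", {
  # symmetric box about the mean: exact cancellation (antithetic bank)
  comp <- bgg_component(100, 12, 1.7, bgg_support(100 - 30, 100 + 30))
  expect_equal(mean_correction(comp, mc_bank(comp, 1e4, 5)), 0)
  # support entirely above the mean region: all sgn(u - S) = -1
  comp2 <- bgg_component(50.000001, 10, 2, bgg_support(50, 300))
  r2 <- mean_correction(comp2, mc_bank(comp2, 1e4, 5))
  expect_lt(r2, 0)
  # MC spread shrinks like 1/sqrt(O) on an asymmetric box
  comp3 <- bgg_component(100, 12, 2, bgg_support(95, 130))
  spread <- function(O) {
    vals <- sapply(1:20, function(s) mean_correction(comp3, mc_bank(comp3, O, s)))
    stats::sd(vals)
  }
  s1 <- spread(400); s2 <- spread(1600)
  expect_equal(s1 / s2, 2, tolerance = 0.8)
})

test_that("scale_correction: zero under no truncation, negative for tight box", {
  for (lam in c(1, 2, 4)) {
    comp <- bgg_component(100, 10, lam, bgg_support(-Inf, Inf))
    expect_equal(scale_correction(comp, mc_bank(comp, 1e4, 7)), 0)
  }
  tight <- bgg_component(100, 10, 2, bgg_support(99, 101))
  g <- scale_correction(tight, mc_bank(tight, 1e4, 7))
  expect_lt(g, -0.9)  # in-support samples have tiny deviations
})

test_that("update_means matches oracles", {
  vals <- matrix(c(10, 20, 60), ncol = 1)
  eta <- matrix(1, 3, 1)
  # shape 2, wide support: responsibility-weighted average
  comp <- bgg_component(30, 20, 2, wide_support(30, 20, 12))
  mix <- bgg_mixture(list(comp), 1)
  banks <- mixture_banks(mix, 1e4, 9)
  u <- update_means(vals, eta, mix, banks)
  expect_equal(u[1, 1], 30, tolerance = 1e-9)
  # weighted version
  eta2 <- matrix(c(0.2, 0.3, 0.5), 3, 1)
  u2 <- update_means(vals, eta2, mix, banks)
  expect_equal(u2[1, 1], sum(eta2 * vals) / sum(eta2), tolerance = 1e-9)
  # all pixels at one value
  u3 <- update_means(matrix(42, 5, 1), matrix(1, 5, 1), mix, banks)
  expect_equal(u3[1, 1], 42, tolerance = 1e-9)
  # shape 4: direct fixed-point formula oracle (R = 0 on a wide box)
  comp4 <- bgg_component(30, 20, 4, wide_support(30, 20, 12))
  mix4 <- bgg_mixture(list(comp4), 1)
  banks4 <- mixture_banks(mix4, 1e4, 9)
  u4 <- update_means(vals, eta, mix4, banks4)
  w <- abs(vals - 30)^2           # |I - u|^(shape-2)
  expect_equal(u4[1, 1], sum(w * vals) / sum(w), tolerance = 1e-6)
})

test_that("update_scales matches oracles", {
  vals <- matrix(c(0, 10), ncol = 1)
  eta <- matrix(1, 2, 1)
  # shape 2, wide support: weighted standard deviation about the mean
  comp <- bgg_component(5, 4, 2, wide_support(5, 4, 20))
  mix <- bgg_mixture(list(comp), 1)
  banks <- mixture_banks(mix, 1e4, 15)
  s <- update_scales(vals, eta, mix, banks)
  expect_equal(s[1, 1], sqrt(mean((vals - 5)^2)), tolerance = 1e-9)
  # shape 1: hand evaluation of the printed formula, beta(1) = sqrt(2)
  comp1 <- bgg_component(5, 4, 1, wide_support(5, 4, 50))
  mix1 <- bgg_mixture(list(comp1), 1)
  banks1 <- mixture_banks(mix1, 1e4, 15)
  s1 <- update_scales(vals, eta, mix1, banks1)
  expect_equal(s1[1, 1], 1 * sqrt(2) * sum(abs(vals - 5)) / 2, tolerance = 1e-9)
  # degenerate data floors at epsilon
  se <- update_scales(matrix(5, 4, 1), matrix(1, 4, 1), mix, banks)
  expect_equal(se[1, 1], 1e-6)
})

test_that("update_weights averages responsibilities", {
  r <- matrix(c(0.2, 0.5, 0.9, 0.8, 0.5, 0.1), 3, 2)
  expect_equal(update_weights(r), c(1.6, 1.4) / 3, tolerance = 1e-12)
  expect_equal(sum(update_weights(r)), 1, tolerance = 1e-12)
  # hard assignments give cluster proportions
  h <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 4, 2)
  expect_equal(update_weights(h), c(0.5, 0.5))
  # uniform rows give uniform weights
  expect_equal(update_weights(matrix(1 / 3, 5, 3)), rep(1 / 3, 3))
})

test_that("shape_objective is maximized near the data-generating shape", {
  for (lam_true in c(1, 3)) {
    comp_t <- bgg_component(128, 20, lam_true, bgg_support(0, 255))
    X <- simulate_bggmm(4000, bgg_mixture(list(comp_t), 1), 31)
    comp <- bgg_component(128, 20, 2)
    bank <- mc_bank(comp, 1e4, 8)
    eta <- rep(1, nrow(X))
    grid <- seq(0.5, 6, by = 0.25)
    vals <- sapply(grid, function(l) shape_objective(X, eta, comp, bank, l))
    expect_lt(abs(grid[which.max(vals)] - lam_true), 0.75)
  }
  # invariant to adding zero-responsibility pixels
  comp <- bgg_component(128, 20, 2)
  bank <- mc_bank(comp, 1e4, 8)
  X <- matrix(c(100, 120, 140), ncol = 1)
  o1 <- shape_objective(X, c(1, 1, 1), comp, bank, 1.6)
  o2 <- shape_objective(rbind(X, matrix(c(10, 250), ncol = 1)),
                        c(1, 1, 1, 0, 0), comp, bank, 1.6)
  expect_equal(o1, o2, tolerance = 1e-12)
  # continuity in the shape under common random numbers
  os <- sapply(seq(1.99, 2.01, by = 1e-3), function(l)
    shape_objective(X, c(1, 1, 1), comp, bank, l))
  expect_lt(max(abs(diff(os))), 0.05)
})

test_that("update_shapes: step sign follows the objective slope, clipping works", {
  cfg <- em_config(seed = 4)
  # data at shape 1, model at 2: proposed Newton direction is negative
  comp_t <- bgg_component(128, 20, 1, bgg_support(0, 255))
  X <- simulate_bggmm(4000, bgg_mixture(list(comp_t), 1), 33)
  comp <- bgg_component(128, 20, 2)
  mix <- bgg_mixture(list(comp), 1)
  banks <- mixture_banks(mix, 1e4, 4)
  up <- update_shapes(X, matrix(rep(1, nrow(X))), mix, banks, cfg)
  expect_lt(up$shapes[1, 1], 2)
  # data at shape 2: near-stationary, small step
  X2 <- simulate_bggmm(8000, bgg_mixture(list(bgg_component(128, 20, 2)), 1), 34)
  up2 <- update_shapes(X2, matrix(rep(1, nrow(X2))), mix, banks, cfg)
  expect_lt(abs(up2$shapes[1, 1] - 2), 0.1)
  # clipping to the bounds
  cfg_hi <- em_config(seed = 4, shape_bounds = c(1.99, 2.01))
  X4 <- simulate_bggmm(4000, bgg_mixture(list(bgg_component(128, 20, 4)), 1), 35)
  up4 <- update_shapes(X4, matrix(rep(1, nrow(X4))), mix, banks, cfg_hi)
  expect_lte(up4$shapes[1, 1], 2.01)
})

test_that("kmeans_init recovers separated blobs and is deterministic", {
  set.seed(101)
  blob1 <- cbind(rnorm(300, 60, 5), rnorm(300, 40, 5))
  blob2 <- cbind(rnorm(700, 180, 5), rnorm(700, 200, 5))
  X <- rbind(blob1, blob2)
  mix <- kmeans_init(X, 2, seed = 2)
  means <- t(sapply(mix$components, `[[`, "mean"))
  ord <- order(means[, 1])
  expect_lt(max(abs(means[ord[1], ] - c(60, 40))), 1)
  expect_lt(max(abs(means[ord[2], ] - c(180, 200))), 1)
  expect_equal(sort(mix$weights), c(0.3, 0.7), tolerance = 0.02)
  expect_true(all(sapply(mix$components, `[[`, "shape") == 2))
  # M = 1: global mean
  mix1 <- kmeans_init(X, 1, seed = 2)
  expect_equal(mix1$components[[1]]$mean, colMeans(X), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(mix1$weights, 1)
  # determinism
  m1 <- kmeans_init(X, 3, seed = 7); m2 <- kmeans_init(X, 3, seed = 7)
  expect_identical(mixture_to_json(m1), mixture_to_json(m2))
})

test_that("run_em recovers a known 2-component model and ascends", {
  truth <- bgg_mixture(list(bgg_component(c(60), c(10), 2),
                            bgg_component(c(180), c(15), 2)),
                       c(0.4, 0.6))
  X <- simulate_bggmm(1e4, truth, 51)
  init <- kmeans_init(X, 2, seed = 3)
  fit <- run_em(X, init, em_config(t1 = 8, mc_count = 1e4, seed = 5))
  m <- fit$mixture
  ord <- order(sapply(m$components, `[[`, "mean"))
  expect_lt(abs(m$components[[ord[1]]]$mean - 60), 2)
  expect_lt(abs(m$components[[ord[2]]]$mean - 180), 2)
  expect_lt(max(abs(sort(m$weights) - c(0.4, 0.6))), 0.05)
  # likelihood ascent within MC tolerance
  expect_true(all(diff(fit$trace) > -abs(fit$trace[1]) * 1e-4))
  # rows of the final responsibilities sum to 1
  expect_equal(rowSums(fit$responsibilities), rep(1, nrow(X)), tolerance = 1e-12)
})

test_that("run_em with t1 = 0 returns the input unchanged", {
  X <- matrix(c(10, 40, 90, 200), ncol = 1)
  init <- kmeans_init(X, 2, seed = 1)
  fit <- run_em(X, init, em_config(t1 = 0, seed = 2))
  expect_identical(mixture_to_json(fit$mixture), mixture_to_json(init))
})

test_that("recovery bias shrinks as the sample grows", {
  truth <- bgg_mixture(list(bgg_component(80, 12, 2),
                            bgg_component(190, 9, 2)), c(0.5, 0.5))
  err <- sapply(c(1e3, 1e4), function(n) {
    X <- simulate_bggmm(n, truth, 61)
    fit <- run_em(X, kmeans_init(X, 2, seed = 3),
                  em_config(t1 = 5, mc_count = 1e4, seed = 5))
    means <- sort(sapply(fit$mixture$components, `[[`, "mean"))
    mean(abs(means - c(80, 190)))
  })
  expect_lt(err[2], err[1] + 0.5)  # no degradation, typically a clear drop
  expect_lt(err[2], 1)
})

test_that("one Gaussian-case EM cycle reproduces classical GMM updates", {
  truth <- bgg_mixture(list(bgg_component(70, 12, 2),
                            bgg_component(170, 18, 2)), c(0.45, 0.55))
  X <- simulate_bggmm(1000, truth, 71)
  # supports at +-10 sigma so truncation is immaterial
  comps <- list(bgg_component(75, 14, 2, wide_support(75, 14)),
                bgg_component(165, 16, 2, wide_support(165, 16)))
  mix <- bgg_mixture(comps, c(0.5, 0.5))
  banks <- mixture_banks(mix, 1e4, 3)
  resp <- e_step(X, mix, banks)
  # classical oracle from the same responsibilities
  gmm_resp <- {
    d1 <- 0.5 * dnorm(X[, 1], 75, 14); d2 <- 0.5 * dnorm(X[, 1], 165, 16)
    cbind(d1 / (d1 + d2), d2 / (d1 + d2))
  }
  expect_lt(max(abs(resp - gmm_resp)), 1e-3)
  u <- update_means(X, resp, mix, banks)
  mix_u <- bggreg:::mixture_with(mix, means = u)
  banks_u <- bggreg:::refresh_all(banks, mix_u)
  s <- update_scales(X, resp, mix_u, banks_u)
  w <- update_weights(resp)
  for (m in 1:2) {
    uo <- sum(gmm_resp[, m] * X[, 1]) / sum(gmm_resp[, m])
    so <- sqrt(sum(gmm_resp[, m] * (X[, 1] - uo)^2) / sum(gmm_resp[, m]))
    expect_lt(abs(u[m, 1] - uo), 1e-3)
    expect_lt(abs(s[m, 1] - so), 1e-3)
    expect_lt(abs(w[m] - mean(gmm_resp[, m])), 1e-3)
  }
})
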