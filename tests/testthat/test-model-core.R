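# Model core: constants, densities, bounded normalization, sampling.

test_that("shape_constants reproduces the closed-form special cases", {
  k2 <- shape_constants(2, 1)
  expect_equal(k2$beta, 0.5, tolerance = 1e-12)
  expect_equal(k2$alpha, 1 / sqrt(2 * pi), tolerance = 1e-12)
  k1 <- shape_constants(1, 1)
  expect_equal(k1$beta, sqrt(2), tolerance = 1e-12)
  # scale enters alpha only, inversely
  expect_equal(shape_constants(1.7, 4)$alpha,
               shape_constants(1.7, 1)$alpha / 4, tolerance = 1e-12)
  expect_error(shape_constants(-1, 1), "shape")
  expect_error(shape_constants(2, 0), "scale")
})

test_that("unbounded density integrates to 1 for random parameters", {
  set.seed(401)
  for (i in 1:10) {
    comp <- bgg_component(runif(1, 50, 200), runif(1, 2, 30),
                          runif(1, 0.5, 6), bgg_support(-Inf, Inf))
    f <- function(x) exp(ggd_log_density(matrix(x, ncol = 1), comp))
    lim <- comp$mean + c(-60, 60) * comp$scale
    expect_equal(integrate(f, lim[1], lim[2], rel.tol = 1e-9)$value, 1,
                 tolerance = 1e-6)
  }
})

test_that("ggd_log_density: peak value, symmetry, normal limit", {
  comp <- bgg_component(c(100, 50), c(10, 5), c(2, 2), bgg_support(-Inf, Inf))
  k <- shape_constants(comp$shape, comp$scale)
  expect_equal(ggd_log_density(comp$mean, comp), sum(log(k$alpha)))
  d <- c(7, -3)
  expect_equal(ggd_log_density(comp$mean + d, comp),
               ggd_log_density(comp$mean - d, comp))
  # shape 2 equals independent normals
  x <- c(91, 57)
  expect_equal(ggd_log_density(x, comp),
               sum(dnorm(x, comp$mean, comp$scale, log = TRUE)),
               tolerance = 1e-12)
})

test_that("bounded_normalizer matches closed forms and is monotone in the box", {
  comp <- bgg_component(100, 12, 2, bgg_support(-Inf, Inf))
  bank <- mc_bank(comp, 1e4, 11)
  expect_equal(bounded_normalizer(comp, bank), 1)
  # +-1 sigma box around the mean: Phi(1) - Phi(-1)
  comp1 <- bgg_component(100, 12, 2, bgg_support(100 - 12, 100 + 12))
  bank1 <- mc_bank(comp1, 1e4, 11)
  p <- pnorm(1) - pnorm(-1)
  se <- sqrt(p * (1 - p) / (1e4 / 2))  # antithetic pairs share magnitude
  expect_lt(abs(bounded_normalizer(comp1, bank1) - p), 3 * se)
  # widening the box never decreases the normalizer
  z <- sapply(c(1, 2, 5, 20), function(w) {
    cw <- bgg_component(100, 12, 2, bgg_support(100 - w * 12, 100 + w * 12))
    bounded_normalizer(cw, mc_bank(cw, 1e4, 11))
  })
  expect_true(all(diff(z) >= 0))
})

test_that("bgg_density: support truncation, unit integral, Gaussian limit", {
  set.seed(402)
  comp <- bgg_component(120, 15, 1.5, bgg_support(80, 200))
  bank <- mc_bank(comp, 1e5, 5)
  expect_identical(bgg_density(79.9, comp, bank), 0)
  expect_identical(bgg_density(200.1, comp, bank), 0)
  f <- function(x) bgg_density(matrix(x, ncol = 1), comp, bank)
  expect_equal(integrate(f, 80, 200, rel.tol = 1e-8)$value, 1, tolerance = 1e-3)
  # wide-box shape-2 component matches the normal density everywhere inside
  cg <- bgg_component(128, 10, 2, wide_support(128, 10))
  bg <- mc_bank(cg, 1e4, 6)
  xs <- matrix(seq(88, 168, length.out = 41), ncol = 1)
  expect_lt(max(abs(bgg_density(xs, cg, bg) - dnorm(xs[, 1], 128, 10))), 1e-4)
})

test_that("mixture_density degenerates correctly and weights components", {
  comp <- bgg_component(100, 10, 2)
  mix1 <- bgg_mixture(list(comp), 1)
  banks1 <- mixture_banks(mix1, 1e4, 9)
  xs <- matrix(c(60, 100, 140), ncol = 1)
  expect_equal(mixture_density(xs, mix1, banks1),
               bgg_density(xs, comp, banks1[[1L]]))
  # identical components: mixture equals the single density for any weights
  mix2 <- bgg_mixture(list(comp, comp), c(0.3, 0.7))
  banks2 <- mixture_banks(mix2, 1e4, 9)
  expect_equal(mixture_density(xs, mix2, banks2),
               bgg_density(xs, comp, banks2[[1L]]), tolerance = 1e-12)
  # well-separated components: the local one dominates at its mean
  mix3 <- bgg_mixture(list(bgg_component(60, 3, 2), bgg_component(200, 3, 2)),
                      c(0.5, 0.5))
  banks3 <- mixture_banks(mix3, 1e4, 9)
  full <- mixture_density(60, mix3, banks3)
  one <- 0.5 * bgg_density(60, mix3$components[[1L]], banks3[[1L]])
  expect_gt(one / full, 0.99)
})

test_that("sample_ggd moments, symmetry and goodness of fit", {
  comp <- bgg_component(50, 4, 2, bgg_support(-Inf, Inf))
  s <- sample_ggd(comp, 1e5, 21)
  expect_lt(abs(mean(s) - 50), 4 * 4 / sqrt(1e5))
  expect_equal(stats::var(s[, 1]), 16, tolerance = 0.05 * 16)
  expect_lt(abs(mean(s < 50) - 0.5), 3 * 0.5 / sqrt(1e5))
  # heavy tails at shape 1 (Laplace: excess kurtosis 3)
  sl <- sample_ggd(bgg_component(0, 1, 1, bgg_support(-Inf, Inf)), 1e5, 22)
  x <- sl[, 1]
  kurt <- mean((x - mean(x))^4) / stats::var(x)^2 - 3
  expect_gt(kurt, 1)
  # distributional check against the exact CDF
  for (shape in c(1, 2, 3.5)) {
    cc <- bgg_component(10, 2, shape, bgg_support(-Inf, Inf))
    draws <- sample_ggd(cc, 1e5, 23)[, 1]
    ks <- suppressWarnings(
      stats::ks.test(draws, function(q) ggd_cdf(q, 10, 2, shape)))
    expect_gt(ks$p.value, 1e-4)
  }
  # determinism
  expect_identical(sample_ggd(comp, 100, 3), sample_ggd(comp, 100, 3))
})

test_that("mc_bank is deterministic and tracks parameter changes", {
  comp <- bgg_component(c(100, 60), c(10, 4), c(2, 1.3))
  b1 <- mc_bank(comp, 1e3, 7)
  b2 <- mc_bank(comp, 1e3, 7)
  expect_identical(b1$samples, b2$samples)
  expect_identical(dim(b1$samples), c(1000L, 2L))
  # same uniforms, shifted mean: samples shift exactly
  comp2 <- bgg_component(c(110, 60), c(10, 4), c(2, 1.3))
  b3 <- bggreg:::bank_refresh(b1, comp2)
  expect_equal(b3$samples[, 1], b1$samples[, 1] + 10, tolerance = 1e-12)
  expect_identical(b3$samples[, 2], b1$samples[, 2])
})

test_that("log_likelihood: peak value, additivity, permutation invariance", {
  comp <- bgg_component(c(100, 100), c(1, 1), c(2, 2),
                        wide_support(c(100, 100), c(1, 1)))
  mix <- bgg_mixture(list(comp), 1)
  banks <- mixture_banks(mix, 1e4, 13)
  f1 <- matrix(c(100, 100), 1, 2)
  expect_equal(log_likelihood(f1, mix, banks), log(1 / (2 * pi)),
               tolerance = 1e-9)
  set.seed(403)
  vals <- cbind(rnorm(50, 100), rnorm(50, 100))
  l1 <- log_likelihood(vals, mix, banks)
  expect_equal(log_likelihood(rbind(vals, vals), mix, banks), 2 * l1)
  expect_equal(log_likelihood(vals[sample(50), ], mix, banks), l1)
  # far outlier hits the floor rather than -Inf
  clipped <- bgg_component(c(100, 100), c(1, 1), c(2, 2), bgg_support(99, 101))
  mixc <- bgg_mixture(list(clipped), 1)
  bc <- mixture_banks(mixc, 1e4, 13)
  expect_equal(log_likelihood(matrix(c(250, 250), 1, 2), mixc, bc), -745)
})

test_that("type invariants are enforced", {
  expect_error(bgg_support(10, 10), "lower < upper")
  expect_error(bgg_component(300, 10, 2), "inside the support")
  expect_error(bgg_component(100, -1, 2), "scale")
  expect_error(bgg_mixture(list(bgg_component(1, 1, 1)), 0.5), "sum to 1")
  mix <- bgg_mixture(list(bgg_component(10, 1, 2), bgg_component(20, 1, 2)),
                     c(0.25, 0.75))
  expect_equal(sum(mix$weights), 1, tolerance = 1e-12)
  sup <- bgg_support(0, 255)
  expect_true(all(bggreg:::support_indicator(matrix(c(0, 255, 128), 3, 1), sup)))
  expect_false(any(bggreg:::support_indicator(matrix(c(-0.1, 255.3), 2, 1), sup)))
})

test_that("mixture JSON round-trips", {
  mix <- bgg_mixture(list(bgg_component(c(60.5, 20.25), c(10, 5), c(2, 1.5)),
                          bgg_component(c(180, 90), c(15, 7.75), c(2.5, 2))),
                     c(0.375, 0.625))
  js <- mixture_to_json(mix)
  back <- mixture_from_json(js)
  expect_equal(back$weights, mix$weights, tolerance = 0)
  for (m in 1:2) {
    expect_identical(back$components[[m]]$mean, mix$components[[m]]$mean)
    expect_identical(back$components[[m]]$scale, mix$components[[m]]$scale)
    expect_identical(back$components[[m]]$shape, mix$components[[m]]$shape)
  }
  # file round-trip
  p <- tempfile(fileext = ".json")
  on.exit(unlink(p))
  mixture_to_json(mix, p)
  expect_equal(mixture_from_json(p)$weights, mix$weights)
})
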