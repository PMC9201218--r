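# Shared fixtures: all built in code at test time.

# Draw n points from a bounded GG mixture by rejection sampling inside
# the support (exact for the truncated model).
simulate_bggmm <- function(n, mixture, seed) {
  comps <- mixture$components
  z <- with_seed_test(seed, sample(seq_along(comps), n, TRUE, prob = mixture$weights))
  out <- matrix(0, n, length(comps[[1L]]$mean))
  for (m in seq_along(comps)) {
    need <- which(z == m)
    i <- 0L
    while (length(need)) {
      i <- i + 1L
      draw <- sample_ggd(comps[[m]], length(need), seed + 7919L * m + i)
      ok <- rowSums(sweep(draw, 2, comps[[m]]$support$lower, `>=`) &
                    sweep(draw, 2, comps[[m]]$support$upper, `<=`)) == ncol(draw)
      out[need[ok], ] <- draw[ok, , drop = FALSE]
      need <- need[!ok]
    }
  }
  out
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Exact CDF of the (unbounded) generalized Gaussian, used as a
# goodness-of-fit oracle against sample_ggd.
ggd_cdf <- function(q, mean, scale, shape) {
  k <- shape_constants(shape, scale)
  0.5 + 0.5 * sign(q - mean) *
    pgamma(k$beta * (abs(q - mean) / scale)^shape, shape = 1 / shape)
}

# Small smooth test image: one Gaussian blob on a ramp.
blob_image <- function(n = 64, cx = 0.5, cy = 0.5, amp = 180, s = 0.2) {
  xs <- matrix(rep(seq(0, 1, length.out = n), each = n), n, n)
  ys <- matrix(rep(seq(0, 1, length.out = n), times = n), n, n)
  pmin(pmax(30 * xs + amp * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * s^2)), 0), 255)
}

wide_support <- function(mean, scale, k = 10) {
  bgg_support(mean - k * scale, mean + k * scale)
}
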