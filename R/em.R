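# EM estimation of the bounded generalized Gaussian mixture on a fixed
# joint intensity field (density-estimation phase).

#' EM configuration
#'
#' @param t1 number of EM cycles per call to [run_em()].
#' @param mc_count Monte-Carlo bank size `O` per component (the
#'   reference protocol uses 1e6; 1e4 is the desk-scale default).
#' @param seed integer seed; all bank randomness derives from it.
#' @param tolerance relative log-likelihood change for early stopping.
#' @param shape_bounds closed interval to which shape parameters are
#'   clipped.
#' @param damping initial Newton damping for the shape step; doubled on
#'   non-improving steps.
#' @param epsilon guard for `|I-u|` powers at shapes below 2.
#' @return list of class `em_config`.
#' @export
em_config <- function(t1 = 5L, mc_count = 1e4, seed = 1L,
                      tolerance = 1e-5, shape_bounds = c(0.2, 10),
                      damping = 1.0, epsilon = 1e-6) {
  stopifnot(t1 >= 0, mc_count >= 2, tolerance > 0,
            length(shape_bounds) == 2L, shape_bounds[1L] > 0,
            shape_bounds[1L] < shape_bounds[2L], damping > 0, epsilon > 0)
  structure(list(t1 = as.integer(t1), mc_count = mc_count,
                 seed = as.integer(seed), tolerance = tolerance,
                 shape_bounds = as.double(shape_bounds),
                 damping = damping, epsilon = epsilon),
            class = "em_config")
}

#' Read an EM configuration from a JSON file
#'
#' Recognized keys: `t1`, `mc_count`, `seed`, `tolerance`,
#' `shape_bounds`, `damping`, `epsilon`; missing keys fall back to the
#' [em_config()] defaults.
#'
#' @param path JSON file path.
#' @return an `em_config`.
#' @export
em_config_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  defaults <- em_config()
  for (k in names(doc)) defaults[[k]] <- doc[[k]]
  do.call(em_config, defaults[c("t1", "mc_count", "seed", "tolerance",
                                "shape_bounds", "damping", "epsilon")])
}

#' E-step: posterior cluster responsibilities
#'
#' Computes \eqn{\eta(z_{xm}) \propto \tau_m BG_m(I_x)} in log space via
#' log-sum-exp.  Pixels at which every component has zero density get a
#' uniform row `1/M` (with a warning).
#'
#' @param field a [joint_field()] or n x C matrix.
#' @param mixture a [bgg_mixture()].
#' @param banks banks from [mixture_banks()].
#' @return X x M responsibility matrix; rows sum to 1.
#' @export
e_step <- function(field, mixture, banks) {
  values <- field_values(field)
  L <- component_log_density_matrix(values, mixture, banks)
  L <- sweep(L, 2L, log(mixture$weights), `+`)
  ll <- logsumexp_rows(L)
  dead <- !is.finite(ll)
  resp <- exp(L - ifelse(is.finite(ll), ll, 0))
  if (any(dead)) {
    warning(sprintf("%d pixel(s) with zero density under every component; using uniform responsibilities", sum(dead)))
    resp[dead, ] <- 1 / mixture$M
  }
  resp
}

# ---- Monte-Carlo truncation corrections ---------------------------------

#' Mean-update truncation correction R
#'
#' Self-normalized Monte-Carlo average of
#' \eqn{\mathrm{sgn}(u - S)\,|S - u|^{\Lambda-1}} over in-support bank
#' samples, per channel.  The signum convention is \eqn{\pm 1} (the
#' derivative of the absolute value), so a support symmetric about the
#' mean cancels exactly under the antithetic bank.
#'
#' @param component a [bgg_component()].
#' @param bank its current [mc_bank()].
#' @return numeric vector, one correction per channel.
#' @export
mean_correction <- function(component, bank) {
  fl <- bank_inflags(bank, component)
  C <- ncol(bank$U)
  out <- numeric(C)
  for (c in seq_len(C)) {
    lam <- component$shape[c]
    d <- bank$mag[, c]^(lam - 1)
    nin <- sum(fl$up[, c]) + sum(fl$dn[, c])
    if (nin == 0) stop("degenerate component: no in-support samples for the mean correction")
    # sgn(u - S) is -1 on the plus branch (S = u + d), +1 on the minus branch
    out[c] <- (sum(d[fl$dn[, c]]) - sum(d[fl$up[, c]])) / nin
  }
  out
}

#' Scale-update truncation correction G
#'
#' Self-normalized Monte-Carlo average of
#' \eqn{-1 + \Lambda\beta\,|S-u|^\Lambda \sigma^{-\Lambda}} over
#' in-support samples, per channel, with the full-bank mean (whose
#' expectation is exactly zero) subtracted as a control variate.  With
#' unbounded or untruncated support the correction is exactly zero.
#'
#' @inheritParams mean_correction
#' @return numeric vector, one correction per channel.
#' @export
scale_correction <- function(component, bank) {
  fl <- bank_inflags(bank, component)
  C <- ncol(bank$U)
  out <- numeric(C)
  for (c in seq_len(C)) {
    lam <- component$shape[c]
    # beta * |S-u|^lam / sigma^lam equals the underlying gamma draw
    phi <- -1 + lam * bank$g[, c]
    nin <- sum(fl$up[, c]) + sum(fl$dn[, c])
    if (nin == 0) stop("degenerate component: no in-support samples for the scale correction")
    mean_in <- (sum(phi[fl$up[, c]]) + sum(phi[fl$dn[, c]])) / nin
    out[c] <- mean_in - mean(phi)
  }
  out
}

# ---- M-step updates ------------------------------------------------------

#' Mean update
#'
#' Fixed-point update
#' \deqn{u^{t+1} = \frac{\sum_x \eta\,(|I-u^t|^{\Lambda-2} I + R)}{\sum_x \eta\,|I-u^t|^{\Lambda-2}}}
#' per channel, with `|I-u|` floored at `epsilon` when the shape is
#' below 2, and the result clamped into the support box.  A vanishing
#' denominator keeps the previous mean.
#'
#' @param field a [joint_field()] or matrix.
#' @param responsibilities X x M matrix from [e_step()].
#' @param mixture a [bgg_mixture()].
#' @param banks current banks.
#' @param epsilon guard for the `|I-u|` power.
#' @return M x C matrix of updated means.
#' @export
update_means <- function(field, responsibilities, mixture, banks,
                         epsilon = 1e-6) {
  values <- field_values(field)
  C <- ncol(values)
  out <- matrix(0, mixture$M, C)
  for (m in seq_len(mixture$M)) {
    comp <- mixture$components[[m]]
    eta <- responsibilities[, m]
    R <- tryCatch(mean_correction(comp, banks[[m]]), error = function(e) {
      bgg_log("mean update: %s (component %d frozen)", conditionMessage(e), m)
      NULL
    })
    if (is.null(R)) { out[m, ] <- comp$mean; next }
    for (c in seq_len(C)) {
      lam <- comp$shape[c]
      dev <- abs(values[, c] - comp$mean[c])
      if (lam < 2) dev <- pmax(dev, epsilon)
      w <- eta * dev^(lam - 2)
      den <- sum(w)
      if (!is.finite(den) || den <= 0) {
        bgg_log("mean update: zero denominator for component %d channel %d", m, c)
        out[m, c] <- comp$mean[c]
      } else {
        out[m, c] <- (sum(w * values[, c]) + R[c] * sum(eta)) / den
      }
      out[m, c] <- clamp(out[m, c], comp$support$lower[c], comp$support$upper[c])
    }
  }
  out
}

#' Scale update
#'
#' \deqn{\sigma^{t+1} = \left[\frac{\Lambda\beta(\Lambda)\sum_x \eta |I-u|^\Lambda}
#'   {\sum_x \eta\,(1 + G)}\right]^{1/\Lambda}}
#' per channel, floored at `epsilon`; a non-positive bracket keeps the
#' previous scale.
#'
#' @inheritParams update_means
#' @return M x C matrix of updated scales.
#' @export
update_scales <- function(field, responsibilities, mixture, banks,
                          epsilon = 1e-6) {
  values <- field_values(field)
  C <- ncol(values)
  out <- matrix(0, mixture$M, C)
  for (m in seq_len(mixture$M)) {
    comp <- mixture$components[[m]]
    eta <- responsibilities[, m]
    G <- tryCatch(scale_correction(comp, banks[[m]]), error = function(e) {
      bgg_log("scale update: %s (component %d frozen)", conditionMessage(e), m)
      NULL
    })
    if (is.null(G)) { out[m, ] <- comp$scale; next }
    k <- shape_constants(comp$shape, comp$scale)
    for (c in seq_len(C)) {
      lam <- comp$shape[c]
      num <- lam * k$beta[c] * sum(eta * abs(values[, c] - comp$mean[c])^lam)
      den <- sum(eta) * (1 + G[c])
      if (!is.finite(den) || den <= 0 || num < 0) {
        bgg_log("scale update: non-positive bracket for component %d channel %d", m, c)
        out[m, c] <- comp$scale[c]
      } else {
        # zero-deviation data legitimately collapses to the floor
        out[m, c] <- max((num / den)^(1 / lam), epsilon)
      }
    }
  }
  out
}

# Objective for one channel at a trial shape, with the bank regenerated
# for the trial under the same uniforms (common random numbers); the
# in-support count is evaluated through the probability-integral
# transform, which is identical to materializing the trial bank.
channel_shape_objective <- function(absdev, eta, sigma, trial, bank, channel,
                                    lower, upper, mean) {
  k <- shape_constants(trial, sigma)
  data_term <- sum(eta * (log(k$alpha) - k$beta * (absdev / sigma)^trial))
  U <- bank$U[, channel]
  thr_up <- (upper - mean) / sigma
  thr_dn <- (mean - lower) / sigma
  p_up <- if (is.finite(thr_up)) stats::pgamma(k$beta * thr_up^trial, shape = 1 / trial) else 1
  p_dn <- if (is.finite(thr_dn)) stats::pgamma(k$beta * thr_dn^trial, shape = 1 / trial) else 1
  z <- (sum(U <= p_up) + sum(U <= p_dn)) / (2 * length(U))
  data_term - sum(eta) * log(max(z, NORMALIZER_FLOOR))
}

#' Shape-dependent part of the expected complete-data objective
#'
#' \eqn{\sum_x \eta_x [\log T(I_x;\Lambda) - \log Z(\Lambda)]} summed
#' over channels, where the bounded-support normalizer \eqn{Z} is
#' re-estimated at the trial shape from the bank's fixed uniform stream
#' (common random numbers), so the objective is smooth in the shape.
#'
#' @param field a [joint_field()] or matrix.
#' @param responsibilities responsibility vector \eqn{\eta} for this
#'   component (length X), or an X x M matrix together with `m`.
#' @param component a [bgg_component()].
#' @param bank the component's [mc_bank()].
#' @param shape trial shape, scalar (recycled) or per-channel vector.
#' @param m column of `responsibilities` to use when a matrix is given.
#' @return scalar objective value.
#' @export
shape_objective <- function(field, responsibilities, component, bank, shape,
                            m = NULL) {
  values <- field_values(field)
  eta <- if (is.matrix(responsibilities)) responsibilities[, m %||% 1L] else responsibilities
  C <- ncol(values)
  shape <- rep_len(shape, C)
  tot <- 0
  for (c in seq_len(C)) {
    tot <- tot + channel_shape_objective(
      abs(values[, c] - component$mean[c]), eta, component$scale[c],
      shape[c], bank, c,
      component$support$lower[c], component$support$upper[c],
      component$mean[c])
  }
  tot
}

#' Shape update: one damped Newton step per channel
#'
#' First and second derivatives of the shape objective are obtained by
#' central finite differences (step 1e-3) under common random numbers,
#' and one damped Newton step
#' \eqn{\Lambda \leftarrow \Lambda - Q'\,(Q'' - \vartheta)^{-1}} is
#' taken, clipped to `shape_bounds`.  If the proposed step does not
#' increase the objective the shape is kept and the damping doubled.
#'
#' @inheritParams update_means
#' @param config an [em_config()].
#' @param damping optional M x C matrix of per-channel damping values
#'   (defaults to `config$damping` everywhere).
#' @return list with `shapes` (M x C matrix) and `damping` (updated
#'   M x C matrix).
#' @export
update_shapes <- function(field, responsibilities, mixture, banks, config,
                          damping = NULL) {
  values <- field_values(field)
  C <- ncol(values)
  if (is.null(damping)) damping <- matrix(config$damping, mixture$M, C)
  shapes <- matrix(0, mixture$M, C)
  h <- 1e-3
  lo <- config$shape_bounds[1L]; hi <- config$shape_bounds[2L]
  for (m in seq_len(mixture$M)) {
    comp <- mixture$components[[m]]
    eta <- responsibilities[, m]
    for (c in seq_len(C)) {
      lam <- comp$shape[c]
      obj <- function(trial) channel_shape_objective(
        abs(values[, c] - comp$mean[c]), eta, comp$scale[c], trial,
        banks[[m]], c, comp$support$lower[c], comp$support$upper[c],
        comp$mean[c])
      f0 <- obj(lam); fp <- obj(lam + h); fm <- obj(max(lam - h, lo / 2))
      q1 <- (fp - fm) / (2 * h)
      q2 <- (fp - 2 * f0 + fm) / h^2
      new_lam <- lam
      if (is.finite(q1) && is.finite(q2)) {
        # damped Newton: double the damping until the step improves the
        # objective (Levenberg-style); give up after 20 doublings
        for (try in 1:20) {
          denom <- q2 - damping[m, c]
          if (!is.finite(denom) || denom >= 0) { damping[m, c] <- damping[m, c] * 2; next }
          cand <- clamp(lam - q1 / denom, lo, hi)
          if (is.finite(cand) && cand != lam && obj(cand) > f0) {
            new_lam <- cand
            # relax the damping again after a productive step
            damping[m, c] <- max(damping[m, c] / 2, config$damping)
            break
          }
          damping[m, c] <- damping[m, c] * 2
        }
      }
      shapes[m, c] <- new_lam
    }
  }
  list(shapes = shapes, damping = damping)
}

#' Weight update
#'
#' \eqn{\tau_m = X^{-1} \sum_x \eta(z_{xm})}.
#'
#' @param responsibilities X x M matrix.
#' @return weight vector on the simplex.
#' @export
update_weights <- function(responsibilities) {
  w <- colMeans(responsibilities)
  w / sum(w)
}

# Rebuild a mixture with (some) parameter blocks replaced; means are
# clamped into the support.
mixture_with <- function(mixture, means = NULL, scales = NULL,
                         shapes = NULL, weights = NULL) {
  comps <- lapply(seq_len(mixture$M), function(m) {
    k <- mixture$components[[m]]
    bgg_component(
      mean = if (is.null(means)) k$mean else clamp(means[m, ], k$support$lower, k$support$upper),
      scale = if (is.null(scales)) k$scale else scales[m, ],
      shape = if (is.null(shapes)) k$shape else shapes[m, ],
      support = k$support)
  })
  bgg_mixture(comps, weights %||% mixture$weights)
}

#' K-means initialization of the mixture
#'
#' Runs k-means with M clusters on the joint intensity vectors; cluster
#' centers become the component means, per-channel within-cluster
#' standard deviations (floored at 1 intensity unit) the scales, cluster
#' proportions the weights; all shapes start at 2 (the Gaussian case).
#'
#' @param field a [joint_field()] or matrix with at least M rows.
#' @param M number of components.
#' @param seed integer seed (k-means restarts included).
#' @param support support box for all components.
#' @return a [bgg_mixture()].
#' @export
kmeans_init <- function(field, M, seed = 1L, support = bgg_support(0, 255)) {
  values <- field_values(field)
  X <- nrow(values)
  if (X < M) stop("need at least M pixels to initialize M components")
  uq <- unique(values)
  M_eff <- min(M, nrow(uq))
  km <- NULL
  for (try in 1:5) {
    km <- with_seed(derive_seed(seed, 31L, try), tryCatch(
      stats::kmeans(values, centers = M_eff, nstart = 3L, iter.max = 100L),
      error = function(e) NULL))
    if (!is.null(km)) break
  }
  if (is.null(km)) { # fall back to seeded distinct centers
    idx <- with_seed(derive_seed(seed, 37L), sample(nrow(uq), M_eff))
    km <- stats::kmeans(values, centers = uq[idx, , drop = FALSE], iter.max = 100L)
  }
  C <- ncol(values)
  comps <- vector("list", M_eff)
  w <- numeric(M_eff)
  for (m in seq_len(M_eff)) {
    rows <- km$cluster == m
    ctr <- clamp(km$centers[m, ], support$lower, support$upper)
    sds <- apply(values[rows, , drop = FALSE], 2L, stats::sd)
    sds[!is.finite(sds)] <- 0
    comps[[m]] <- bgg_component(ctr, pmax(sds, 1), rep(2, C), support)
    w[m] <- mean(rows)
  }
  # pad with duplicated components if distinct data could not fill M
  while (length(comps) < M) {
    comps[[length(comps) + 1L]] <- comps[[1L]]
    w <- c(w, 1e-6)
  }
  bgg_mixture(comps, w / sum(w))
}

#' Run the EM density-estimation cycles
#'
#' Executes `t1` cycles of E-step, mean, scale, shape and weight
#' updates, regenerating the Monte-Carlo banks (from the same seed
#' stream) after each parameter change, and stops early when the
#' relative log-likelihood change falls below the tolerance.  A
#' component whose bank degenerates has its weight driven to zero and
#' its parameters frozen.
#'
#' @param field a [joint_field()] or matrix.
#' @param mixture initialized [bgg_mixture()].
#' @param config an [em_config()].
#' @param banks optional pre-built banks (rebuilt from `config` if
#'   omitted).
#' @param damping optional damping state from a previous call.
#' @return list with elements `mixture`, `trace` (per-cycle
#'   log-likelihood, starting at the input model), `responsibilities`
#'   (final E-step), `banks`, `damping`.
#' @export
run_em <- function(field, mixture, config = em_config(), banks = NULL,
                   damping = NULL) {
  values <- field_values(field)
  if (is.null(banks)) banks <- mixture_banks(mixture, config$mc_count, config$seed)
  if (is.null(damping)) damping <- matrix(config$damping, mixture$M, ncol(values))
  trace <- log_likelihood(values, mixture, banks)
  resp <- NULL
  if (config$t1 > 0) {
    for (it in seq_len(config$t1)) {
      resp <- e_step(values, mixture, banks)

      means <- update_means(values, resp, mixture, banks, config$epsilon)
      mixture <- mixture_with(mixture, means = means)
      banks <- refresh_all(banks, mixture)

      scales <- update_scales(values, resp, mixture, banks, config$epsilon)
      mixture <- mixture_with(mixture, scales = scales)
      banks <- refresh_all(banks, mixture)

      sh <- update_shapes(values, resp, mixture, banks, config, damping)
      damping <- sh$damping
      mixture <- mixture_with(mixture, shapes = sh$shapes)
      banks <- refresh_all(banks, mixture)

      w <- update_weights(resp)
      mixture <- mixture_with(mixture, weights = w)

      trace <- c(trace, log_likelihood(values, mixture, banks))
      n <- length(trace)
      rel <- abs(trace[n] - trace[n - 1L]) / max(abs(trace[n - 1L]), 1)
      if (rel < config$tolerance) break
    }
    resp <- e_step(values, mixture, banks)
  }
  list(mixture = mixture, trace = trace, responsibilities = resp,
       banks = banks, damping = damping)
}

refresh_all <- function(banks, mixture) {
  for (m in seq_len(mixture$M))
    banks[[m]] <- bank_refresh(banks[[m]], mixture$components[[m]])
  banks
}
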