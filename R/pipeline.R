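# Multiresolution orchestration: k-means init, alternating EM and
# linearized motion phases, coarse-to-fine.

#' Separable Gaussian blur with reflected borders
#'
#' @param image numeric matrix.
#' @param sigma standard deviation in pixels; `sigma <= 0` returns the
#'   image unchanged.
#' @return blurred matrix.
#' @export
gaussian_blur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  reflect <- function(idx, n) { # reflect indices into 1..n
    idx <- abs(idx - 1L) + 1L
    over <- idx > n
    idx[over] <- 2L * n - idx[over] + 1L
    clamp(idx, 1L, n)
  }
  H <- nrow(image); W <- ncol(image)
  tmp <- matrix(0, H, W)
  for (j in -r:r)
    tmp <- tmp + k[j + r + 1L] * image[, reflect(seq_len(W) + j, W)]
  out <- matrix(0, H, W)
  for (j in -r:r)
    out <- out + k[j + r + 1L] * tmp[reflect(seq_len(H) + j, H), ]
  out
}

#' Resize an image by a scale factor
#'
#' Downscaling applies Gaussian anti-aliasing (sigma = 0.5/scale) before
#' bilinear resampling with aligned pixel centers.
#'
#' @param image numeric matrix.
#' @param scale positive scale factor; 1 returns the image unchanged.
#' @return resized matrix.
#' @export
resize_image <- function(image, scale) {
  stopifnot_positive(scale, "scale")
  if (scale == 1) return(image)
  H <- nrow(image); W <- ncol(image)
  Hn <- max(4L, round(H * scale)); Wn <- max(4L, round(W * scale))
  src <- image
  if (scale < 1) src <- gaussian_blur(image, 0.5 / scale)
  ry <- H / Hn; rx <- W / Wn
  sy <- ( (0:(Hn - 1)) + 0.5) * ry - 0.5
  sx <- ( (0:(Wn - 1)) + 0.5) * rx - 0.5
  gx <- rep(sx, each = Hn)
  gy <- rep(sy, times = Wn)
  matrix(bilinear_sample(src, gx, gy), Hn, Wn)
}

#' Rescale a transform between pyramid levels
#'
#' Translations are multiplied by `to_scale / from_scale`; the angle is
#' unchanged (rotation about the image center commutes with uniform
#' scaling).
#'
#' @param transform a [rigid_transform()].
#' @param from_scale,to_scale positive scales.
#' @return rescaled `rigid2d`.
#' @export
rescale_transform <- function(transform, from_scale, to_scale) {
  stopifnot_positive(from_scale, "from_scale")
  stopifnot_positive(to_scale, "to_scale")
  s <- to_scale / from_scale
  rigid_transform(transform$tx * s, transform$ty * s, transform$angle)
}

#' Registration configuration
#'
#' @param components number of mixture components M (the reference
#'   protocol uses 6).
#' @param resolutions strictly increasing scale factors ending at 1.
#' @param em an [em_config()] used for the density phases (its seed is
#'   re-derived per level from `seed`).
#' @param t2 motion steps per alternation round.
#' @param outer_iterations maximum alternation rounds per level.
#' @param increment_tolerance convergence threshold on the motion-step
#'   norm (pixels/degrees).
#' @param seed master seed for every random choice.
#' @param max_fit_pixels density estimation subsamples the joint field
#'   to at most this many pixels per round (full field used for the
#'   motion solve).
#' @param weighting increment weighting, see [solve_increment()].
#' @param search_range `c(translation, rotation)` bounds (full-resolution
#'   pixels / degrees) inside which the transform is kept; defaults to
#'   1.5 times the experimental generation ranges.
#' @param grid_init run a global grid initialization over the search
#'   range at the coarse levels, scored by profile likelihood, before
#'   local refinement (recommended: the linearized increments are local).
#' @param noise_floor net per-round motion below which a level is
#'   declared stalled (the Monte-Carlo jitter of the EM refits sets a
#'   floor around 0.1 px/deg; lower it for asymptotic-accuracy studies).
#' @return list of class `registration_config`.
#' @export
registration_config <- function(components = 6L,
                                resolutions = c(0.1, 0.2, 1),
                                em = em_config(),
                                t2 = 10L,
                                outer_iterations = 20L,
                                increment_tolerance = 1e-3,
                                seed = 1L,
                                max_fit_pixels = 6000L,
                                weighting = c("derived", "as-printed"),
                                search_range = c(30, 15),
                                grid_init = TRUE,
                                noise_floor = 0.1) {
  stopifnot(components >= 1, t2 >= 1, outer_iterations >= 1,
            increment_tolerance > 0, max_fit_pixels >= 10,
            length(search_range) == 2L, all(search_range > 0))
  if (is.unsorted(resolutions, strictly = TRUE) || utils::tail(resolutions, 1L) != 1)
    stop("resolutions must be strictly increasing and end at 1")
  structure(list(components = as.integer(components),
                 resolutions = as.double(resolutions),
                 em = em, t2 = as.integer(t2),
                 outer_iterations = as.integer(outer_iterations),
                 increment_tolerance = increment_tolerance,
                 seed = as.integer(seed),
                 max_fit_pixels = as.integer(max_fit_pixels),
                 weighting = match.arg(weighting),
                 search_range = as.double(search_range),
                 grid_init = isTRUE(grid_init),
                 noise_floor = as.double(noise_floor)),
            class = "registration_config")
}

clamp_transform <- function(theta, scale, range) {
  rigid_transform(clamp(theta$tx, -range[1L] * scale, range[1L] * scale),
                  clamp(theta$ty, -range[1L] * scale, range[1L] * scale),
                  clamp(theta$angle, -range[2L], range[2L]))
}

# Global initialization at the coarsest level: rank a transform grid
# spanning the generation ranges under the incoming mixture, then
# re-score a shortlist by profile likelihood (fresh k-means + short EM
# per candidate) and return the winner with its fitted mixture.
grid_init_level <- function(pl, theta0, mixture, banks, config, scale) {
  tr_max <- min(config$search_range[1L] * scale,
                (min(dim(pl$reference)) - 4) / 2)
  txs <- unique(clamp(seq(-tr_max, tr_max, length.out = 9L), -tr_max, tr_max))
  angs <- seq(-config$search_range[2L], config$search_range[2L], length.out = 7L)
  cand <- expand.grid(tx = txs, ty = txs, a = angs)
  cand <- rbind(c(theta0$tx, theta0$ty, theta0$angle), cand)
  score1 <- vapply(seq_len(nrow(cand)), function(i) {
    th <- rigid_transform(cand$tx[i], cand$ty[i], cand$a[i])
    f <- tryCatch(build_joint_field(pl, th), error = function(e) NULL)
    if (is.null(f) || f$count < 16) return(-Inf)
    log_likelihood(f, mixture, banks) / f$count
  }, 0)
  short <- utils::head(order(score1, decreasing = TRUE), 8L)
  em_cfg <- config$em
  em_cfg$t1 <- 2L
  # candidate scoring is a ranking, not an estimate: a small bank is
  # plenty and keeps the initializer cheap
  em_cfg$mc_count <- min(em_cfg$mc_count, 2000)
  best <- list(score = -Inf, theta = theta0, mixture = mixture)
  for (i in short) {
    th <- rigid_transform(cand$tx[i], cand$ty[i], cand$a[i])
    f <- tryCatch(build_joint_field(pl, th), error = function(e) NULL)
    if (is.null(f) || f$count < 16) next
    mx <- tryCatch(kmeans_init(f, config$components,
                               derive_seed(config$seed, 13L, i)),
                   error = function(e) NULL)
    if (is.null(mx)) next
    fit <- run_em(f, mx, em_cfg)
    sc <- utils::tail(fit$trace, 1L) / f$count
    if (sc > best$score) best <- list(score = sc, theta = th, mixture = fit$mixture)
  }
  best
}

# Deterministic, spatially uniform subsample (every k-th valid pixel):
# stable across alternation rounds, so the EM refits do not inject
# sampling jitter into the motion target.
subsample_field <- function(field, max_rows, seed = NULL) {
  if (field$count <= max_rows) return(field)
  idx <- unique(round(seq(1L, field$count, length.out = max_rows)))
  joint_field(field$values[idx, , drop = FALSE])
}

# Expected complete-data objective with fixed responsibilities:
# sum_x sum_m eta_xm [log tau_m + log BG_m(I_x)].
q_surrogate_rows <- function(values, resp, mixture, banks) {
  L <- component_log_density_matrix(values, mixture, banks)
  L <- sweep(L, 2L, log(mixture$weights), `+`)
  rowSums(resp * pmax(L, LOG_DENSITY_FLOOR))
}

q_surrogate <- function(values, resp, mixture, banks) {
  sum(q_surrogate_rows(values, resp, mixture, banks))
}

#' Register a floating image to a reference image
#'
#' Runs the full coarse-to-fine algorithm: at every resolution level the
#' images are downsampled (anti-aliased), the incoming transform is
#' rescaled, the mixture is initialized by k-means at the first level
#' (warm-started thereafter), and rounds of `t1` EM cycles followed by
#' `t2` damped linearized motion steps alternate until the motion
#' increment norm falls below the tolerance or the round budget is
#' exhausted.  Deterministic given the configuration seed.
#'
#' @param pair an [image_pair()] (reference, floating).
#' @param config a [registration_config()].
#' @param init optional initial [rigid_transform()] in full-resolution
#'   pixels (default identity).
#' @param truth optional ground-truth transform; when given, the
#'   result's `pad` element reports the PAD error.
#' @return Object of class `registration_result` with elements
#'   `transform`, `likelihood_trace` (one vector per level),
#'   `level_transforms`, `converged`, `iterations_used`, `mixture`, and
#'   optionally `pad`.
#' @export
register_images <- function(pair, config = registration_config(),
                            init = rigid_transform(), truth = NULL) {
  res <- config$resolutions
  nlev <- length(res)
  theta <- rescale_transform(init, 1, res[1L])
  mixture <- NULL; damping <- NULL
  traces <- vector("list", nlev)
  level_transforms <- vector("list", nlev)
  iterations <- integer(nlev)
  converged <- logical(nlev)

  for (l in seq_len(nlev)) {
    s <- res[l]
    if (l > 1L) theta <- rescale_transform(theta, res[l - 1L], s)
    pl <- image_pair(clamp(resize_image(pair$reference, s), 0, 255),
                     clamp(resize_image(pair$floating, s), 0, 255))
    field <- tryCatch(build_joint_field(pl, theta), error = function(e)
      stop(sprintf("empty overlap at pyramid level %d (scale %.3g)", l, s), call. = FALSE))
    em_cfg <- config$em
    em_cfg$seed <- derive_seed(config$seed, 7L, l)
    if (is.null(mixture)) {
      mixture <- kmeans_init(subsample_field(field, config$max_fit_pixels),
                             config$components, derive_seed(config$seed, 5L))
    }
    if (config$grid_init && min(dim(pl$reference)) <= 32) {
      # the linearized increments are local; seed the coarse levels with
      # a global search over the admissible transform range (the
      # incoming transform competes as a candidate)
      pre <- run_em(field, mixture, local({ e <- config$em; e$t1 <- 2L; e }))
      g <- grid_init_level(pl, theta, pre$mixture, pre$banks, config, s)
      theta <- g$theta
      mixture <- g$mixture
    }
    banks <- NULL
    trace <- numeric(0)
    prev_small <- FALSE
    for (round in seq_len(config$outer_iterations)) {
      field <- tryCatch(build_joint_field(pl, theta), error = function(e)
        stop(sprintf("empty overlap at pyramid level %d (scale %.3g)", l, s), call. = FALSE))
      fit <- run_em(subsample_field(field, config$max_fit_pixels),
                    mixture, em_cfg, banks = banks, damping = damping)
      mixture <- fit$mixture; damping <- fit$damping; banks <- fit$banks
      trace <- c(trace, fit$trace)

      net <- c(0, 0, 0)
      last_norm <- Inf
      H <- nrow(pl$reference); W <- ncol(pl$reference)
      for (t in seq_len(config$t2)) {
        wcur <- warp_image(pl$floating, theta)
        if (!any(wcur$valid)) stop(sprintf("empty overlap at pyramid level %d (scale %.3g)", l, s))
        jac_full <- intensity_jacobian(pl, theta)
        # the solve and the acceptance test run on a pixel subset: the
        # increment is a weighted average, statistically stable well
        # below the full pixel count
        vidx <- which(wcur$valid)
        if (length(vidx) > config$max_fit_pixels) {
          rows <- unique(round(seq(1L, length(vidx),
                                   length.out = config$max_fit_pixels)))
          vidx <- vidx[rows]
        } else rows <- seq_along(vidx)
        vals_t <- cbind(pl$reference[vidx], wcur$image[vidx])
        resp <- e_step(vals_t, mixture, banks)
        inc <- solve_increment(joint_field(vals_t),
                               list(jac = jac_full$jac[rows, , drop = FALSE]),
                               resp, mixture, config$weighting,
                               config$em$epsilon)
        # guard against wild solves before damping
        nrm <- increment_norm(inc)
        if (nrm > 10) inc <- motion_increment(10 * inc$dtx / nrm, 10 * inc$dty / nrm,
                                              10 * inc$dangle / nrm)
        # damped acceptance: halve a step that lowers the fixed-eta Q
        # surrogate, compared over the common valid-pixel subset
        pts <- cbind((vidx - 1L) %/% H, (vidx - 1L) %% H)
        l_cur <- q_surrogate_rows(vals_t, resp, mixture, banks)
        accepted <- FALSE
        scale_fac <- 1
        for (halve in 0:5) {
          cand <- rigid_transform(theta$tx + inc$dtx * scale_fac,
                                  theta$ty + inc$dty * scale_fac,
                                  theta$angle + inc$dangle * scale_fac)
          wc <- warp_at(pl$floating, cand, pts)
          if (any(wc$valid)) {
            keep <- wc$valid
            vals_c <- cbind(pl$reference[vidx[keep]], wc$values[keep])
            eta_t <- resp[keep, , drop = FALSE]
            q_cand <- sum(q_surrogate_rows(vals_c, eta_t, mixture, banks))
            if (q_cand >= sum(l_cur[keep]) - 1e-9) { accepted <- TRUE; break }
          }
          scale_fac <- scale_fac / 2
        }
        # a rejected step ends the motion block but is not convergence:
        # the next round's EM refit may open up further progress
        if (!accepted) { last_norm <- Inf; break }
        applied <- motion_increment(inc$dtx * scale_fac, inc$dty * scale_fac,
                                    inc$dangle * scale_fac)
        theta <- clamp_transform(cand, s, config$search_range)
        net <- net + c(applied$dtx, applied$dty, applied$dangle)
        last_norm <- increment_norm(applied)
        if (last_norm < max(config$increment_tolerance, config$noise_floor / 5))
          break
      }
      iterations[l] <- round
      net_norm <- sqrt(sum(net^2))
      # a level is done when a whole alternation round (EM refit plus
      # motion block) no longer moves the transform; the Monte-Carlo
      # jitter of the refits sets a noise floor (~0.1 px/deg) under
      # which further rounds only jitter the estimate
      if (net_norm < max(config$increment_tolerance, config$noise_floor)) {
        converged[l] <- TRUE
        break
      }
    }
    traces[[l]] <- trace
    level_transforms[[l]] <- theta
  }

  out <- list(transform = theta, likelihood_trace = traces,
              level_transforms = level_transforms, converged = all(converged),
              level_converged = converged, iterations_used = iterations,
              mixture = mixture, seed = config$seed)
  if (!is.null(truth)) out$pad <- pad(theta, truth, pair$dim)
  structure(out, class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> tx=%.3f ty=%.3f angle=%.3f deg (%s)\n",
              x$transform$tx, x$transform$ty, x$transform$angle,
              if (x$converged) "converged" else "round budget reached"))
  if (!is.null(x$pad)) cat(sprintf("  PAD vs truth: %.4f px\n", x$pad))
  invisible(x)
}
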