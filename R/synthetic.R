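# Phantom generation, the perturbation protocol and the PAD metric.

#' Generate a synthetic phantom pair
#'
#' The reference is a seeded composition of smooth Gaussian blobs,
#' filled ellipses and a half-plane edge, lightly smoothed and rescaled
#' to span `[0, 255]`.  A monomodal pair duplicates the reference; a
#' multimodal pair passes it through a monotone nonlinear intensity
#' remap followed by a non-monotone band inversion (emulating, e.g.,
#' MR-T1 versus MR-T2 contrast reversal), so the joint intensity scatter
#' forms several clusters while the geometry is untouched.
#'
#' @param size image side in pixels (at least 64).
#' @param seed integer seed; the same seed reproduces the pair exactly.
#' @param modality `"monomodal"` or `"multimodal"`.
#' @return an [image_pair()] in perfect alignment (identity truth).
#' @export
generate_phantom <- function(size = 128L, seed = 1L,
                             modality = c("monomodal", "multimodal")) {
  modality <- match.arg(modality)
  if (size < 64) stop("phantom size must be at least 64")
  base <- with_seed(derive_seed(seed, 41L), {
    n <- as.integer(size)
    xs <- matrix(rep(seq(0, 1, length.out = n), each = n), n, n)
    ys <- matrix(rep(seq(0, 1, length.out = n), times = n), n, n)
    img <- 15 * xs + 10 * ys                      # gentle background ramp
    for (b in 1:6) {
      cx <- stats::runif(1, 0.15, 0.85); cy <- stats::runif(1, 0.15, 0.85)
      s <- stats::runif(1, 0.07, 0.18); amp <- stats::runif(1, 60, 150)
      img <- img + amp * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * s^2))
    }
    for (e in 1:2) {
      cx <- stats::runif(1, 0.25, 0.75); cy <- stats::runif(1, 0.25, 0.75)
      rx <- stats::runif(1, 0.10, 0.28); ry <- stats::runif(1, 0.10, 0.28)
      amp <- stats::runif(1, 40, 90)
      img <- img + amp * (((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1)
    }
    a <- stats::runif(1, -1, 1); b <- stats::runif(1, -1, 1)
    img <- img + 40 * (a * (xs - 0.5) + b * (ys - 0.5) >= 0)
    img <- gaussian_blur(img, 1.5)
    # dark surround, as in radiographs/MR slices: a smooth window taking
    # the intensity to zero at the borders (also avoids artificial edges
    # where a transformed image runs out of support)
    edge <- pmin(xs, 1 - xs, ys, 1 - ys)
    win <- pmin(edge / 0.1, 1)^2 * (3 - 2 * pmin(edge / 0.1, 1))
    img <- img * win
    rng <- range(img)
    255 * (img - rng[1L]) / (rng[2L] - rng[1L])
  })
  floating <- if (modality == "monomodal") base else multimodal_remap(base)
  image_pair(base, floating)
}

# Monotone gamma-like remap plus inversion of one intensity band; keeps
# the mapping piecewise so the joint scatter has several clusters.
multimodal_remap <- function(image) {
  v <- 255 * (image / 255)^0.65
  band <- v >= 90 & v <= 170
  v[band] <- 260 - v[band]
  clamp(v, 0, 255)
}

#' Draw a random rigid transform from the experimental ranges
#'
#' Translations uniform on `[-20, 20]` pixels (each axis), rotation
#' uniform on `[-10, 10]` degrees.
#'
#' @param seed integer seed.
#' @return a [rigid_transform()].
#' @export
random_transform <- function(seed = 1L) {
  with_seed(derive_seed(seed, 43L), {
    rigid_transform(stats::runif(1, -20, 20), stats::runif(1, -20, 20),
                    stats::runif(1, -10, 10))
  })
}

#' Add zero-mean Gaussian noise on the unit intensity scale
#'
#' The image is scaled to `[0, 1]`, additive N(0, variance) noise is
#' applied, the result clipped back to `[0, 1]` and rescaled to
#' `[0, 255]`.  The protocol range for the variance is 0 to 0.04.
#'
#' @param image numeric matrix in `[0, 255]`.
#' @param variance noise variance on the unit scale, in `[0, 0.04]`.
#' @param seed integer seed.
#' @return noisy matrix in `[0, 255]`.
#' @export
add_noise <- function(image, variance, seed = 1L) {
  if (!is_scalar_num(variance) || variance < 0 || variance > 0.04)
    stop("noise variance must lie in [0, 0.04] (unit intensity scale)")
  if (variance == 0) return(image)
  u <- image / 255
  noise <- with_seed(derive_seed(seed, 47L),
                     matrix(stats::rnorm(length(u), 0, sqrt(variance)),
                            nrow(u), ncol(u)))
  255 * clamp(u + noise, 0, 1)
}

#' Average pixel displacement between two transforms
#'
#' Mean over the pixel grid of the Euclidean distance between the two
#' transforms' mappings of each pixel.  Zero iff the transforms map
#' every grid point identically; a pure-translation discrepancy gives
#' its Euclidean norm exactly, independent of the image size.  Values
#' above 3 are conventionally treated as registration failure.
#'
#' @param estimated,truth [rigid_transform()] objects.
#' @param shape image dimensions `c(H, W)`.
#' @return nonnegative scalar (pixels).
#' @export
pad <- function(estimated, truth, shape) {
  H <- shape[1L]; W <- shape[2L]
  pts <- cbind(rep(0:(W - 1), each = H), rep(0:(H - 1), times = W))
  d <- transform_points(estimated, pts, shape) - transform_points(truth, pts, shape)
  mean(sqrt(rowSums(d^2)))
}

#' Run the perturbation sweep protocol
#'
#' For every level x seed cell, perturbs the pair (random transform plus
#' noise for the `"noise"` protocol; a pure `(t, t)` pixel shift for the
#' `"displacement"` protocol), registers, and records the PAD against
#' the known truth.  Individual failures are recorded (`NA` pad), not
#' fatal.  The same seeds are reused at every level (paired design).
#'
#' @param pair base [image_pair()] in perfect alignment.
#' @param protocol `"noise"` (levels are unit-scale variances, 0-0.04)
#'   or `"displacement"` (levels are shifts `t` in pixels, 0-30).
#' @param levels numeric vector of protocol levels.
#' @param seeds integer vector of run seeds.
#' @param config a [registration_config()] (its seed is re-derived per
#'   run).
#' @return data.frame with columns `level`, `seed`, `pad`, `converged`,
#'   `runtime`.
#' @export
sweep_registration <- function(pair, protocol = c("noise", "displacement"),
                               levels, seeds, config = registration_config()) {
  protocol <- match.arg(protocol)
  rows <- vector("list", length(levels) * length(seeds))
  i <- 0L
  for (lv in levels) {
    for (sd in seeds) {
      i <- i + 1L
      t0 <- proc.time()[["elapsed"]]
      row <- tryCatch({
        if (protocol == "noise") {
          truth <- random_transform(sd)
          flt <- warp_image(pair$floating, invert_transform(truth), fill = 0)$image
          flt <- add_noise(flt, lv, seed = derive_seed(sd, 53L))
        } else {
          if (lv < 0 || lv > 30) stop("displacement level outside 0-30")
          truth <- rigid_transform(lv, lv, 0)
          flt <- warp_image(pair$floating, invert_transform(truth), fill = 0)$image
        }
        cfg <- config
        cfg$seed <- derive_seed(config$seed, 59L, sd)
        res <- register_images(image_pair(pair$reference, flt), cfg, truth = truth)
        data.frame(level = lv, seed = sd, pad = res$pad,
                   converged = res$converged,
                   runtime = proc.time()[["elapsed"]] - t0)
      }, error = function(e) {
        bgg_log("sweep cell (level=%g, seed=%d) failed: %s", lv, sd,
                conditionMessage(e))
        data.frame(level = lv, seed = sd, pad = NA_real_, converged = FALSE,
                   runtime = proc.time()[["elapsed"]] - t0)
      })
      rows[[i]] <- row
    }
  }
  do.call(rbind, rows)
}
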