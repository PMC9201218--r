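#' Bounded support region for intensity vectors
#'
#' A closed axis-aligned box in intensity space.  Component densities
#' are truncated to this box and renormalized; membership is inclusive
#' at both ends.  The default `[0, 255]` per channel matches 8-bit
#' grayscale images.
#'
#' @param lower,upper numeric vectors (one entry per channel);
#'   `lower < upper` elementwise.  Scalars are recycled.
#' @return An object of class `bgg_support`.
#' @export
#' @examples
#' bgg_support(0, 255)
bgg_support <- function(lower = 0, upper = 255) {
  n <- max(length(lower), length(upper))
  lower <- rep_len(as.double(lower), n)
  upper <- rep_len(as.double(upper), n)
  if (any(!is.finite(lower) & lower != -Inf) || any(!is.finite(upper) & upper != Inf))
    stop("support bounds must be finite or infinite numerics")
  if (any(lower >= upper)) stop("support requires lower < upper on every channel")
  structure(list(lower = lower, upper = upper), class = "bgg_support")
}

#' @export
print.bgg_support <- function(x, ...) {
  cat("<bgg_support> [", paste(x$lower, collapse = ", "), "] .. [",
      paste(x$upper, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

support_indicator <- function(values, support) {
  # values: n x C matrix; returns logical n-vector (inside closed box)
  values <- as_matrix_rows(values)
  inside <- rep(TRUE, nrow(values))
  for (c in seq_len(ncol(values)))
    inside <- inside & values[, c] >= support$lower[c] & values[, c] <= support$upper[c]
  inside
}

as_matrix_rows <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

#' Single bounded generalized Gaussian component
#'
#' Channels are modelled as independent generalized Gaussian factors
#' (diagonal model): each channel has its own mean \eqn{u}, scale
#' \eqn{\sigma > 0} and shape \eqn{\Lambda > 0}, truncated to the
#' support box.  \eqn{\Lambda = 2} is the Gaussian special case,
#' \eqn{\Lambda = 1} the Laplace case.
#'
#' @param mean numeric vector of per-channel means; must lie inside the
#'   support (clamped by EM updates, validated here).
#' @param scale positive per-channel scale.
#' @param shape positive per-channel shape exponent.
#' @param support a [bgg_support()]; scalars recycled to the channel count.
#' @return An object of class `bgg_component`.
#' @export
#' @examples
#' bgg_component(mean = c(60, 180), scale = c(10, 15), shape = 2)
bgg_component <- function(mean, scale, shape, support = bgg_support(0, 255)) {
  C <- max(length(mean), length(scale), length(shape))
  mean <- rep_len(as.double(mean), C)
  scale <- rep_len(as.double(scale), C)
  shape <- rep_len(as.double(shape), C)
  stopifnot_positive(scale, "scale")
  stopifnot_positive(shape, "shape")
  if (length(support$lower) != C)
    support <- bgg_support(rep_len(support$lower, C), rep_len(support$upper, C))
  if (any(mean < support$lower | mean > support$upper))
    stop("component mean must lie inside the support box")
  structure(list(mean = mean, scale = scale, shape = shape, support = support),
            class = "bgg_component")
}

#' @export
print.bgg_component <- function(x, ...) {
  cat("<bgg_component> u=(", paste(signif(x$mean, 5), collapse = ", "),
      ") sigma=(", paste(signif(x$scale, 5), collapse = ", "),
      ") shape=(", paste(signif(x$shape, 5), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Mixture of bounded generalized Gaussian components
#'
#' @param components list of [bgg_component()] objects, all with the
#'   same channel count.
#' @param weights mixing proportions; nonnegative, summing to 1 within
#'   1e-12 (renormalized exactly).
#' @return Object of class `bgg_mixture` with elements `components`,
#'   `weights`, and `M`.
#' @export
bgg_mixture <- function(components, weights) {
  if (!length(components)) stop("mixture needs at least one component")
  if (!all(vapply(components, inherits, TRUE, "bgg_component")))
    stop("components must be bgg_component objects")
  C <- length(components[[1L]]$mean)
  if (!all(vapply(components, function(k) length(k$mean), 1L) == C))
    stop("all components must share the channel count")
  weights <- as.double(weights)
  if (length(weights) != length(components)) stop("one weight per component")
  if (any(weights < 0) || any(!is.finite(weights))) stop("weights must be >= 0")
  s <- sum(weights)
  if (abs(s - 1) > 1e-6) stop("weights must sum to 1")
  weights <- weights / s
  structure(list(components = components, weights = weights,
                 M = length(components), channels = C),
            class = "bgg_mixture")
}

#' @export
print.bgg_mixture <- function(x, ...) {
  cat(sprintf("<bgg_mixture> M=%d, %d channel(s)\n", x$M, x$channels))
  for (m in seq_len(x$M)) {
    cat(sprintf("  [%d] w=%.4f ", m, x$weights[m])); print(x$components[[m]])
  }
  invisible(x)
}

#' Normalizing constants of the (unbounded) generalized Gaussian
#'
#' Returns the pair \eqn{(\alpha, \beta)} of the density
#' \eqn{T(x) = \alpha \exp(-\beta |x-u|^\Lambda / \sigma^\Lambda)} with
#' \deqn{\alpha = \frac{\Lambda \sqrt{\Gamma(3/\Lambda)}}{2 \sigma \Gamma(1/\Lambda)^{3/2}},
#'       \qquad \beta = \left[\frac{\Gamma(3/\Lambda)}{\Gamma(1/\Lambda)}\right]^{\Lambda/2},}
#' chosen so that \eqn{T} integrates to one over the real line and
#' \eqn{\sigma} is the standard deviation.  At \eqn{\Lambda = 2} this is
#' the normal density, at \eqn{\Lambda = 1} the Laplace density.
#' Computed through `lgamma` for stability at small shapes.
#'
#' @param shape positive shape exponent(s) \eqn{\Lambda}.
#' @param scale positive scale(s) \eqn{\sigma}.
#' @return list with numeric elements `alpha` and `beta` (vectorized).
#' @export
#' @examples
#' shape_constants(2, 1)  # alpha = 1/sqrt(2*pi), beta = 1/2
shape_constants <- function(shape, scale) {
  stopifnot_positive(shape, "shape")
  stopifnot_positive(scale, "scale")
  lg3 <- lgamma(3 / shape)
  lg1 <- lgamma(1 / shape)
  beta <- exp((shape / 2) * (lg3 - lg1))
  alpha <- exp(log(shape) + 0.5 * lg3 - log(2 * scale) - 1.5 * lg1)
  list(alpha = alpha, beta = beta)
}

#' Log density of the unbounded generalized Gaussian factor model
#'
#' Per-channel log of \eqn{T} summed across channels; no support
#' truncation is applied.
#'
#' @param value numeric vector (one pixel) or n x C matrix of intensity
#'   vectors.
#' @param component a [bgg_component()].
#' @return numeric vector of log densities (length n).
#' @export
ggd_log_density <- function(value, component) {
  v <- as_matrix_rows(value)
  if (ncol(v) != length(component$mean))
    stop("value has wrong channel count")
  k <- shape_constants(component$shape, component$scale)
  out <- numeric(nrow(v))
  for (c in seq_len(ncol(v))) {
    z <- abs(v[, c] - component$mean[c]) / component$scale[c]
    out <- out + log(k$alpha[c]) - k$beta[c] * z^component$shape[c]
  }
  out
}

# ---- Monte-Carlo sample banks -------------------------------------------

#' Draw i.i.d. samples from the unbounded generalized Gaussian
#'
#' Gamma-transform sampler: with \eqn{G \sim \mathrm{Gamma}(1/\Lambda, 1)}
#' and a uniform random sign \eqn{s}, \eqn{x = u + s\,\sigma (G/\beta)^{1/\Lambda}}
#' follows \eqn{T}.  Deterministic given `seed`.
#'
#' @param component a [bgg_component()].
#' @param n number of draws.
#' @param seed integer seed.
#' @return n x C matrix of draws.
#' @export
sample_ggd <- function(component, n, seed = 1L) {
  stopifnot(n >= 1)
  C <- length(component$mean)
  k <- shape_constants(component$shape, component$scale)
  with_seed(seed, {
    out <- matrix(0, n, C)
    for (c in seq_len(C)) {
      g <- stats::rgamma(n, shape = 1 / component$shape[c], rate = 1)
      s <- sample(c(-1, 1), n, replace = TRUE)
      out[, c] <- component$mean[c] +
        s * component$scale[c] * (g / k$beta[c])^(1 / component$shape[c])
    }
    out
  })
}

#' Monte-Carlo sample bank for a component
#'
#' Holds `count` draws per channel from the component's unbounded
#' density \eqn{T}, used to estimate the bounded-support normalizer and
#' the truncation corrections of the EM updates.  Draws are generated by
#' the inverse-CDF gamma transform from a fixed uniform stream, in
#' antithetic pairs \eqn{u \pm d}: the uniforms depend only on `seed`,
#' so a bank regenerated after a parameter change reuses the same
#' underlying randomness (common random numbers), which keeps the shape
#' objective smooth in \eqn{\Lambda} and makes symmetric-support
#' corrections cancel exactly.
#'
#' @param component a [bgg_component()].
#' @param count number of samples `O` (rounded up to an even number).
#'   The reference protocol value is 1e6 (the default); the fitting
#'   routines use the desk-scale 1e4 of [em_config()].
#' @param seed integer seed; same seed and parameters give identical
#'   samples.
#' @return Object of class `bgg_mc_bank` with elements `samples`
#'   (O x C matrix), `count`, `seed`, plus internal fields reused by the
#'   EM routines.
#' @export
mc_bank <- function(component, count = 1e6, seed = 1L) {
  stopifnot(count >= 2)
  half <- ceiling(count / 2)
  C <- length(component$mean)
  U <- with_seed(seed, matrix(stats::runif(half * C), half, C))
  bank <- structure(list(U = U, count = 2L * half, seed = as.integer(seed),
                         g = NULL, mag = NULL, samples = NULL,
                         shape = NULL, mean = NULL, scale = NULL),
                    class = "bgg_mc_bank")
  bank_refresh(bank, component)
}

# Recompute the transformed samples for the current component
# parameters; qgamma is only re-evaluated when the shape changed.
bank_refresh <- function(bank, component) {
  C <- ncol(bank$U)
  k <- shape_constants(component$shape, component$scale)
  if (is.null(bank$g) || !identical(bank$shape, component$shape)) {
    g <- bank$g %||% matrix(0, nrow(bank$U), C)
    for (c in seq_len(C)) {
      if (is.null(bank$shape) || bank$shape[c] != component$shape[c])
        g[, c] <- stats::qgamma(bank$U[, c], shape = 1 / component$shape[c], rate = 1)
    }
    bank$g <- g
  }
  mag <- matrix(0, nrow(bank$U), C)
  for (c in seq_len(C))
    mag[, c] <- component$scale[c] * (bank$g[, c] / k$beta[c])^(1 / component$shape[c])
  bank$mag <- mag
  bank$samples <- rbind(sweep(mag, 2, component$mean, function(d, u) u + d),
                        sweep(mag, 2, component$mean, function(d, u) u - d))
  bank$shape <- component$shape
  bank$mean <- component$mean
  bank$scale <- component$scale
  bank$support <- component$support
  bank$infrac <- NULL
  bank$infrac <- bank_infractions(bank, component)
  bank
}

#' @export
print.bgg_mc_bank <- function(x, ...) {
  cat(sprintf("<bgg_mc_bank> O=%d, %d channel(s), seed=%d\n",
              x$count, ncol(x$U), x$seed))
  invisible(x)
}

# Per-channel in-support flags for the antithetic halves.
bank_inflags <- function(bank, component) {
  C <- ncol(bank$U)
  sup <- component$support
  up <- matrix(FALSE, nrow(bank$U), C)   # u + d inside
  dn <- matrix(FALSE, nrow(bank$U), C)   # u - d inside
  for (c in seq_len(C)) {
    up[, c] <- bank$mag[, c] <= (sup$upper[c] - component$mean[c])
    dn[, c] <- bank$mag[, c] <= (component$mean[c] - sup$lower[c])
  }
  list(up = up, dn = dn)
}

# Per-channel in-support fraction estimates (cached at refresh time).
bank_infractions <- function(bank, component) {
  if (!is.null(bank$infrac) && identical(bank$mean, component$mean) &&
      identical(bank$scale, component$scale) &&
      identical(bank$shape, component$shape) &&
      identical(bank$support, component$support))
    return(bank$infrac)
  fl <- bank_inflags(bank, component)
  (colSums(fl$up) + colSums(fl$dn)) / bank$count
}

#' Monte-Carlo estimate of the bounded-support normalizer
#'
#' Estimates the mass of the unbounded density inside the support box as
#' the fraction of bank samples falling inside, per channel, multiplied
#' across channels (diagonal factor model).  Floored at 1e-12 to guard
#' division; a bank entirely outside the support raises a degenerate
#' component error.
#'
#' @param component a [bgg_component()].
#' @param bank an [mc_bank()] drawn from the component's current
#'   parameters.
#' @return scalar in (0, 1].
#' @export
bounded_normalizer <- function(component, bank) {
  frac <- bank_infractions(bank, component)
  if (all(frac == 0))
    stop("degenerate component: no Monte-Carlo samples inside the support")
  max(prod(pmax(frac, NORMALIZER_FLOOR)), NORMALIZER_FLOOR)
}

#' Bounded generalized Gaussian density
#'
#' \eqn{BG(x) = T(x) H(x) / Z} where \eqn{H} is the support indicator
#' and \eqn{Z} the Monte-Carlo [bounded_normalizer()]; zero outside the
#' support, integrates to one over it.
#'
#' @inheritParams bounded_normalizer
#' @param value intensity vector or n x C matrix.
#' @return numeric vector of densities.
#' @export
bgg_density <- function(value, component, bank) {
  z <- bounded_normalizer(component, bank)
  dens <- exp(ggd_log_density(value, component)) / z
  dens[!support_indicator(value, component$support)] <- 0
  dens
}

#' Mixture density of the bounded generalized Gaussian mixture
#'
#' @param value intensity vector or n x C matrix.
#' @param mixture a [bgg_mixture()].
#' @param banks list of [mc_bank()] objects, one per component (see
#'   [mixture_banks()]).
#' @return numeric vector of mixture densities.
#' @export
mixture_density <- function(value, mixture, banks) {
  v <- as_matrix_rows(value)
  out <- numeric(nrow(v))
  for (m in seq_len(mixture$M))
    out <- out + mixture$weights[m] *
      bgg_density(v, mixture$components[[m]], banks[[m]])
  out
}

#' Build one Monte-Carlo bank per mixture component
#'
#' @param mixture a [bgg_mixture()].
#' @param count samples per bank.
#' @param seed base seed; each component gets a derived child seed.
#' @return list of `bgg_mc_bank` objects.
#' @export
mixture_banks <- function(mixture, count = 1e4, seed = 1L) {
  lapply(seq_len(mixture$M), function(m)
    mc_bank(mixture$components[[m]], count, derive_seed(seed, 17L, m)))
}

# X x M matrix of per-component log bounded densities (with -Inf outside
# support replaced by the log floor at the likelihood level only).
component_log_density_matrix <- function(values, mixture, banks) {
  values <- as_matrix_rows(values)
  X <- nrow(values)
  L <- matrix(0, X, mixture$M)
  for (m in seq_len(mixture$M)) {
    comp <- mixture$components[[m]]
    z <- tryCatch(bounded_normalizer(comp, banks[[m]]), error = function(e) NA_real_)
    if (is.na(z)) { L[, m] <- -Inf; next }   # degenerate component: zero density
    ld <- ggd_log_density(values, comp) - log(z)
    ld[!support_indicator(values, comp$support)] <- -Inf
    L[, m] <- ld
  }
  L
}

logsumexp_rows <- function(L) {
  mx <- apply(L, 1L, max)
  bad <- !is.finite(mx)
  mx[bad] <- 0
  out <- mx + log(rowSums(exp(L - mx)))
  out[bad] <- -Inf
  out
}

#' Data log-likelihood of a joint intensity field under the mixture
#'
#' Sum over valid pixels of the log mixture density, computed in log
#' space via log-sum-exp.  Pixels with zero mixture density contribute
#' the log-density floor (-745) instead of -Inf.
#'
#' @param field a [joint_field()] (or bare n x C matrix of intensity
#'   vectors).
#' @param mixture a [bgg_mixture()].
#' @param banks list of banks from [mixture_banks()].
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(field, mixture, banks) {
  values <- field_values(field)
  L <- component_log_density_matrix(values, mixture, banks)
  L <- sweep(L, 2L, log(mixture$weights), `+`)
  ll <- logsumexp_rows(L)
  sum(pmax(ll, LOG_DENSITY_FLOOR))
}

# ---- JSON serialization --------------------------------------------------

#' Serialize a mixture to JSON
#'
#' Writes keys `M`, `weights`, `means`, `scales`, `shapes`, `support`
#' (rows indexed by component).  Round-trips exactly for
#' decimal-representable values.
#'
#' @param mixture a [bgg_mixture()].
#' @param path optional file path; if `NULL`, the JSON string is
#'   returned.
#' @return JSON string (invisibly, if written to a file).
#' @export
mixture_to_json <- function(mixture, path = NULL) {
  per <- function(fld) lapply(mixture$components, function(k) k[[fld]])
  sup <- mixture$components[[1L]]$support
  doc <- list(M = mixture$M,
              weights = mixture$weights,
              means = per("mean"), scales = per("scale"), shapes = per("shape"),
              support = list(lower = sup$lower, upper = sup$upper))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Deserialize a mixture from JSON
#'
#' @param x JSON string or path to a JSON file written by
#'   [mixture_to_json()].
#' @return a [bgg_mixture()].
#' @export
mixture_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x, simplifyVector = TRUE)
  sup <- bgg_support(doc$support$lower, doc$support$upper)
  comps <- lapply(seq_len(doc$M), function(m)
    bgg_component(mean = row_of(doc$means, m), scale = row_of(doc$scales, m),
                  shape = row_of(doc$shapes, m), support = sup))
  bgg_mixture(comps, doc$weights)
}

row_of <- function(x, m) {
  if (is.matrix(x)) x[m, ] else if (is.list(x)) x[[m]] else x[m]
}
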