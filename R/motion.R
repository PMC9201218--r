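# Rigid 2-D transforms, warping, joint intensity fields and the
# linearized motion-increment solve.
#
# Coordinate convention: pixel centers at integer coordinates, 0-based,
# origin at the top-left pixel, x along columns, y along rows; rotation
# in degrees, positive counter-clockwise in (x, y), about the geometric
# image center ((W-1)/2, (H-1)/2).  The transform maps reference-grid
# coordinates to floating-image coordinates (backward warping).

#' Rigid 2-D transform
#'
#' Translation in pixels plus rotation in degrees about the image
#' center.  Acts on coordinates as \eqn{T(p) = R_\phi (p - c) + c + t}.
#'
#' @param tx,ty translation in pixels.
#' @param angle rotation in degrees, counter-clockwise positive.
#' @return Object of class `rigid2d`.
#' @export
#' @examples
#' rigid_transform(3, -4, 2.5)
rigid_transform <- function(tx = 0, ty = 0, angle = 0) {
  stopifnot(is_scalar_num(tx), is_scalar_num(ty), is_scalar_num(angle))
  structure(list(tx = as.double(tx), ty = as.double(ty),
                 angle = as.double(angle)), class = "rigid2d")
}

#' @export
print.rigid2d <- function(x, ...) {
  cat(sprintf("<rigid2d> tx=%.4f ty=%.4f angle=%.4f deg\n", x$tx, x$ty, x$angle))
  invisible(x)
}

#' Motion increment
#'
#' Small additive change of the rigid parameters, as produced by
#' [solve_increment()].
#'
#' @param dtx,dty,dangle finite increments (pixels, pixels, degrees).
#' @return Object of class `motion_increment`.
#' @export
motion_increment <- function(dtx = 0, dty = 0, dangle = 0) {
  v <- c(dtx, dty, dangle)
  if (any(!is.finite(v))) stop("motion increment must be finite")
  structure(list(dtx = as.double(dtx), dty = as.double(dty),
                 dangle = as.double(dangle)), class = "motion_increment")
}

rot_mat <- function(angle_deg) {
  a <- angle_deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)
}

image_center <- function(shape) c((shape[2L] - 1) / 2, (shape[1L] - 1) / 2)

#' Apply a rigid transform to 0-based pixel coordinates
#'
#' @param transform a [rigid_transform()].
#' @param points n x 2 matrix of (x, y) coordinates.
#' @param shape image dimensions `c(H, W)` defining the rotation center.
#' @return n x 2 matrix of mapped coordinates.
#' @export
transform_points <- function(transform, points, shape) {
  points <- as_matrix_rows(points)
  ctr <- image_center(shape)
  R <- rot_mat(transform$angle)
  out <- sweep(points, 2L, ctr) %*% t(R)
  sweep(out, 2L, ctr + c(transform$tx, transform$ty), `+`)
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return the inverse `rigid2d` (about the same center).
#' @export
invert_transform <- function(transform) {
  Rinv <- rot_mat(-transform$angle)
  t2 <- -drop(Rinv %*% c(transform$tx, transform$ty))
  rigid_transform(t2[1L], t2[2L], -transform$angle)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`
#' (both about the same image center): `T2(T1(p))`.
#'
#' @param first,second `rigid2d` objects.
#' @return composed `rigid2d`.
#' @export
compose_transforms <- function(first, second) {
  R2 <- rot_mat(second$angle)
  t <- drop(R2 %*% c(first$tx, first$ty)) + c(second$tx, second$ty)
  rigid_transform(t[1L], t[2L], first$angle + second$angle)
}

#' Reference/floating image pair
#'
#' @param reference,floating numeric matrices of equal size with
#'   intensities in `[0, 255]`.
#' @return Object of class `image_pair`.
#' @export
image_pair <- function(reference, floating) {
  if (!is.matrix(reference) || !is.matrix(floating))
    stop("images must be numeric matrices")
  if (!all(dim(reference) == dim(floating)))
    stop("reference and floating images must have the same size")
  rng <- range(reference, floating)
  if (rng[1L] < -1e-9 || rng[2L] > 255 + 1e-9)
    stop("intensities must lie within [0, 255]")
  structure(list(reference = reference, floating = floating,
                 dim = dim(reference)), class = "image_pair")
}

#' Backward-warp an image under a rigid transform
#'
#' For every output pixel `p`, samples the input image at `T(p)` by
#' bilinear interpolation.  Pixels mapping outside the image are marked
#' invalid.  The identity transform returns the image bit-exactly with a
#' full mask.
#'
#' @param image numeric matrix.
#' @param transform a [rigid_transform()].
#' @param fill value placed at invalid pixels in the returned image
#'   (default `NA`).
#' @return list with `image` (numeric matrix) and `valid` (logical
#'   matrix).
#' @export
warp_image <- function(image, transform, fill = NA_real_) {
  H <- nrow(image); W <- ncol(image)
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), times = W), H, W)
  src <- transform_points(transform, cbind(as.vector(xs), as.vector(ys)), c(H, W))
  sx <- src[, 1L]; sy <- src[, 2L]
  valid <- sx >= 0 & sx <= (W - 1) & sy >= 0 & sy <= (H - 1)
  vals <- bilinear_sample(image, sx, sy, valid)
  vals[!valid] <- fill
  list(image = matrix(vals, H, W), valid = matrix(valid, H, W))
}

# Warp only at selected 0-based (x, y) points; returns values and
# validity.  Same semantics as warp_image restricted to `pts`.
warp_at <- function(image, transform, pts) {
  H <- nrow(image); W <- ncol(image)
  src <- transform_points(transform, pts, c(H, W))
  valid <- src[, 1L] >= 0 & src[, 1L] <= (W - 1) &
           src[, 2L] >= 0 & src[, 2L] <= (H - 1)
  vals <- bilinear_sample(image, src[, 1L], src[, 2L], valid)
  vals[!valid] <- NA_real_
  list(values = vals, valid = valid)
}

# Bilinear sampling at (sx, sy) 0-based coordinates; out-of-range
# entries of `valid` are left untouched (any value).
bilinear_sample <- function(image, sx, sy, valid = NULL) {
  H <- nrow(image); W <- ncol(image)
  if (is.null(valid)) valid <- rep(TRUE, length(sx))
  sxv <- clamp(sx, 0, W - 1); syv <- clamp(sy, 0, H - 1)
  x0 <- floor(sxv); y0 <- floor(syv)
  wx <- sxv - x0; wy <- syv - y0
  x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
  i00 <- y0 + 1 + x0 * H; i10 <- y0 + 1 + x1 * H
  i01 <- y1 + 1 + x0 * H; i11 <- y1 + 1 + x1 * H
  v <- (1 - wy) * ((1 - wx) * image[i00] + wx * image[i10]) +
       wy * ((1 - wx) * image[i01] + wx * image[i11])
  v
}

#' Joint intensity field
#'
#' Per-pixel joint intensity vectors `[reference; warped floating]`
#' restricted to the valid overlap.  Can also wrap a bare n x C matrix
#' of intensity vectors (used by the density-estimation fixtures).
#'
#' @param values n x C numeric matrix of intensity vectors.
#' @param mask optional logical matrix recording which image pixels the
#'   rows came from.
#' @return Object of class `joint_field` with elements `values`, `mask`,
#'   `count`.
#' @export
joint_field <- function(values, mask = NULL) {
  values <- as_matrix_rows(values)
  if (!is.null(mask) && sum(mask) != nrow(values))
    stop("mask cardinality must equal the number of field rows")
  structure(list(values = values, mask = mask, count = nrow(values)),
            class = "joint_field")
}

field_values <- function(field) {
  if (inherits(field, "joint_field")) field$values else as_matrix_rows(field)
}

#' @export
print.joint_field <- function(x, ...) {
  cat(sprintf("<joint_field> X=%d pixels, %d channel(s)\n",
              x$count, ncol(x$values)))
  invisible(x)
}

#' Build the joint intensity field of a pair under a transform
#'
#' Stacks the reference intensity and the warped floating intensity at
#' every valid (overlap) pixel.
#'
#' @param pair an [image_pair()].
#' @param transform a [rigid_transform()] acting on the floating image.
#' @return a [joint_field()] with 2 channels.
#' @export
build_joint_field <- function(pair, transform) {
  w <- warp_image(pair$floating, transform)
  if (!any(w$valid)) stop("empty overlap: transform maps no pixel inside the floating image")
  values <- cbind(pair$reference[w$valid], w$image[w$valid])
  joint_field(values, mask = w$valid)
}

# Central-difference spatial gradient; border pixels use one-sided
# differences.  Returns list(gx, gy).
image_gradient <- function(image) {
  H <- nrow(image); W <- ncol(image)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  if (W >= 3) gx[, 2:(W - 1)] <- (image[, 3:W] - image[, 1:(W - 2)]) / 2
  if (W >= 2) { gx[, 1] <- image[, 2] - image[, 1]; gx[, W] <- image[, W] - image[, W - 1] }
  if (H >= 3) gy[2:(H - 1), ] <- (image[3:H, ] - image[1:(H - 2), ]) / 2
  if (H >= 2) { gy[1, ] <- image[2, ] - image[1, ]; gy[H, ] <- image[H, ] - image[H - 1, ] }
  list(gx = gx, gy = gy)
}

#' Derivative of the joint intensity vector in the motion parameters
#'
#' For each valid pixel, the 2 x 3 Jacobian of `[A; B(T(p))]` with
#' respect to `(tx, ty, angle)`.  The reference row is identically zero
#' (the reference image does not depend on the motion).  The floating
#' row chains the spatial gradient of the warped floating image (central
#' differences) through the coordinate Jacobian of the transform; the
#' angle column is in intensity units per degree.
#'
#' @param pair an [image_pair()].
#' @param transform a [rigid_transform()].
#' @return list with `jac` (X x 3 matrix, floating-channel row per valid
#'   pixel), `valid` (logical matrix matching [build_joint_field()]'s
#'   mask).
#' @export
intensity_jacobian <- function(pair, transform) {
  H <- pair$dim[1L]; W <- pair$dim[2L]
  w <- warp_image(pair$floating, transform, fill = 0)
  g <- image_gradient(w$image)
  # gradient is unreliable where any neighbour was invalid
  er <- function(v) { # erode validity by one pixel (4-neighbourhood)
    out <- v
    out[, -1] <- out[, -1] & v[, -W]; out[, -W] <- out[, -W] & v[, -1]
    out[-1, ] <- out[-1, ] & v[-H, ]; out[-H, ] <- out[-H, ] & v[-1, ]
    out
  }
  gvalid <- er(w$valid)
  a <- cos(transform$angle * pi / 180); b <- sin(transform$angle * pi / 180)
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), times = W), H, W)
  ctr <- image_center(c(H, W))
  dx <- xs - ctr[1L]; dy <- ys - ctr[2L]
  # gradient of B at T(p): rotate the warped-image gradient back
  bx <- g$gx * a - g$gy * b
  by <- g$gx * b + g$gy * a
  deg <- pi / 180
  jx <- bx
  jy <- by
  ja <- deg * (bx * (-b * dx - a * dy) + by * (a * dx - b * dy))
  keep <- w$valid
  jac <- cbind(jx[keep], jy[keep], ja[keep])
  jac[!gvalid[keep], ] <- 0
  list(jac = jac, valid = keep)
}

#' Solve the linearized motion increment
#'
#' Assembles the 3 x 3 normal equations of the linearized expected
#' log-likelihood and solves for the rigid increment.  Only the floating
#' channel contributes (the reference row of the Jacobian is zero).  The
#' per-component channel weight defaults to the objective-consistent
#' form \eqn{\Lambda\beta\, \sigma^{-\Lambda} |I-u|^{\Lambda-2}}
#' (`weighting = "derived"`); `weighting = "as-printed"` uses
#' \eqn{\Lambda\beta\,\sigma^{-1}} for fidelity experiments.  A singular
#' system returns the zero increment.
#'
#' @param field a [joint_field()] built at the current transform.
#' @param jacobian result of [intensity_jacobian()] at the same
#'   transform.
#' @param responsibilities X x M responsibility matrix from [e_step()].
#' @param mixture a [bgg_mixture()].
#' @param weighting `"derived"` (default) or `"as-printed"`.
#' @param epsilon guard for `|I-u|^(shape-2)` when shape < 2.
#' @return a [motion_increment()].
#' @export
solve_increment <- function(field, jacobian, responsibilities, mixture,
                            weighting = c("derived", "as-printed"),
                            epsilon = 1e-6) {
  weighting <- match.arg(weighting)
  values <- field_values(field)
  C <- ncol(values)
  flt <- C            # floating channel is the last one
  J <- jacobian$jac
  X <- nrow(values)
  if (nrow(J) != X || nrow(responsibilities) != X)
    stop("field, jacobian and responsibilities must agree in pixel count")
  a <- numeric(X); r <- numeric(X)
  for (m in seq_len(mixture$M)) {
    comp <- mixture$components[[m]]
    k <- shape_constants(comp$shape[flt], comp$scale[flt])
    lam <- comp$shape[flt]
    resid <- values[, flt] - comp$mean[flt]
    w <- if (weighting == "derived") {
      lam * k$beta * comp$scale[flt]^(-lam) * pmax(abs(resid), epsilon)^(lam - 2)
    } else {
      rep(lam * k$beta / comp$scale[flt], X)
    }
    hw <- responsibilities[, m] * w
    a <- a + hw
    r <- r + hw * resid
  }
  if (any(!is.finite(a)) || any(!is.finite(r)))
    stop("non-finite entries in the increment system")
  Hm <- crossprod(J, J * a)
  rhs <- -colSums(J * r)
  delta <- tryCatch(solve(Hm, rhs), error = function(e) {
    bgg_log("singular increment system; returning zero increment")
    c(0, 0, 0)
  })
  if (rcond_ok(Hm) == FALSE) delta <- c(0, 0, 0)
  motion_increment(delta[1L], delta[2L], delta[3L])
}

rcond_ok <- function(Hm) {
  rc <- tryCatch(rcond(Hm), error = function(e) 0)
  is.finite(rc) && rc > 1e-14
}

#' Apply a motion increment to a transform
#'
#' Componentwise addition of `(tx, ty, angle)`.
#'
#' @param transform a [rigid_transform()].
#' @param increment a [motion_increment()].
#' @return updated `rigid2d`.
#' @export
apply_increment <- function(transform, increment) {
  rigid_transform(transform$tx + increment$dtx,
                  transform$ty + increment$dty,
                  transform$angle + increment$dangle)
}

increment_norm <- function(increment) {
  sqrt(increment$dtx^2 + increment$dty^2 + increment$dangle^2)
}
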