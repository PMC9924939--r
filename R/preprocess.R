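# Image conditioning applied ahead of detection: rolling-ball background
# subtraction, percentile intensity normalization, maximum-intensity
# projection, and Gaussian blur for the 2D culture-image path.

#' Rolling-ball background subtraction
#'
#' Estimates the slowly varying background of a 2D plane as the grayscale
#' opening of the intensity surface with a ball-shaped (spherical-cap)
#' structuring element of the given pixel radius — the morphological
#' formalization of the classic "rolling ball" — and subtracts it. The
#' background is everywhere at most the input, so the output is
#' non-negative. For 3D stacks, apply slice by slice (see
#' [preprocess_stack()]).
#'
#' @param plane 2D numeric matrix, non-negative and finite.
#' @param radius_px ball radius in pixels (default 6).
#' @return matrix of the same shape: `plane - background`.
#' @export
rolling_ball_background <- function(plane, radius_px = 6L) {
  stopifnot(is.matrix(plane), all(is.finite(plane)), all(plane >= 0))
  radius_px <- as.integer(radius_px)
  if (radius_px < 1L) stop("radius_px must be >= 1")
  if (2L * radius_px + 1L > min(dim(plane))) {
    stop("rolling-ball radius exceeds the plane extent")
  }
  se <- ball_structuring_element(radius_px)
  eroded <- gray_morph(plane, se, op = "erode")
  background <- gray_morph(eroded, se, op = "dilate")
  pmax(plane - background, 0)
}

# offsets and heights of the ball SE, normalized so the centre height is 0
ball_structuring_element <- function(r) {
  off <- expand.grid(dy = -r:r, dx = -r:r)
  keep <- off$dx^2 + off$dy^2 <= r^2
  off <- off[keep, ]
  h <- sqrt(r^2 - off$dx^2 - off$dy^2) - r
  list(dx = off$dx, dy = off$dy, h = h)
}

# non-flat grayscale erosion/dilation with replicated-edge padding
gray_morph <- function(plane, se, op = c("erode", "dilate")) {
  op <- match.arg(op)
  ny <- nrow(plane); nx <- ncol(plane)
  out <- array(if (op == "erode") Inf else -Inf, dim = dim(plane))
  for (k in seq_along(se$h)) {
    iy <- pmin(pmax(seq_len(ny) + se$dy[k], 1L), ny)
    ix <- pmin(pmax(seq_len(nx) + se$dx[k], 1L), nx)
    shifted <- plane[iy, ix, drop = FALSE]
    out <- if (op == "erode") {
      pmin(out, shifted - se$h[k])
    } else {
      pmax(out, shifted + se$h[k])
    }
  }
  out
}

#' Percentile (saturation) intensity normalization
#'
#' Linearly rescales intensities so that the `saturation_fraction / 2`
#' and `1 - saturation_fraction / 2` quantiles map to 0 and 1, clipping
#' outside `[0, 1]`. This is the "2% saturated" contrast-normalization
#' convention with the saturated fraction split equally across the two
#' tails.
#'
#' @param image numeric vector/matrix/array, finite.
#' @param saturation_fraction total fraction of pixels saturated
#'   (default 0.02); must be in `[0, 0.5)`.
#' @return rescaled object of the same shape with values in `[0, 1]`.
#'   A degenerate image (upper quantile equal to lower) returns all
#'   zeros with a warning.
#' @export
percentile_normalize <- function(image, saturation_fraction = 0.02) {
  stopifnot(all(is.finite(image)),
            saturation_fraction >= 0, saturation_fraction < 0.5)
  q <- quantile(image, c(saturation_fraction / 2,
                         1 - saturation_fraction / 2), names = FALSE)
  if (q[2L] <= q[1L]) {
    warning("degenerate image: normalization quantiles coincide; returning zeros")
    image[] <- 0
    return(image)
  }
  image[] <- pmin(pmax((image - q[1L]) / (q[2L] - q[1L]), 0), 1)
  image
}

#' Maximum-intensity projection along z
#' @param stack 3D array `(nz, ny, nx)` with `nz >= 1`.
#' @return matrix `(ny, nx)` of per-pixel maxima over z.
#' @export
max_project <- function(stack) {
  stopifnot(length(dim(stack)) == 3L)
  nz <- dim(stack)[1L]
  out <- stack[1L, , ]
  if (nz > 1L) {
    for (k in 2L:nz) out <- pmax(out, stack[k, , ])
  }
  out
}

#' 2D Gaussian blur
#'
#' Separable convolution with a normalized Gaussian kernel under
#' symmetric (reflective) boundary handling, which conserves total
#' intensity. `sigma_px = 0` is the identity.
#'
#' @param plane 2D numeric matrix.
#' @param sigma_px Gaussian standard deviation in pixels.
#' @return blurred matrix of the same shape.
#' @export
gaussian_blur <- function(plane, sigma_px = 1) {
  stopifnot(is.matrix(plane), sigma_px >= 0)
  if (sigma_px == 0) return(plane)
  k <- gaussian_kernel_1d(sigma_px)
  conv_axis(conv_axis(plane, k, 1L), k, 2L)
}

#' Preprocess an image stack for detection
#'
#' Applies, per channel: slice-wise rolling-ball background subtraction,
#' then percentile normalization with quantiles computed either per
#' z-slice or over the whole stack (use [preprocess_section_set()] to
#' pool quantiles across the sections of one animal), then optionally a
#' maximum-intensity projection with a 2D Gaussian blur (the culture
#' pipeline).
#'
#' @param img an [image_stack()]
#' @param rolling_ball_radius_px ball radius in pixels; `0` skips
#'   background subtraction.
#' @param saturation_fraction passed to [percentile_normalize()];
#'   `NULL` skips normalization.
#' @param normalize_scope `"stack"` (quantiles over the full 3D channel)
#'   or `"slice"` (per z-slice).
#' @param projection `"none"` or `"max"`.
#' @param blur_sigma_px Gaussian sd in pixels applied to the projection
#'   (2D path only).
#' @return an [image_stack()]; if projected, a single-slice stack.
#' @export
preprocess_stack <- function(img, rolling_ball_radius_px = 6L,
                             saturation_fraction = 0.02,
                             normalize_scope = c("stack", "slice"),
                             projection = c("none", "max"),
                             blur_sigma_px = 0) {
  stopifnot(inherits(img, "image_stack"))
  normalize_scope <- match.arg(normalize_scope)
  projection <- match.arg(projection)
  nz <- dim(img$intensities)[1L]
  out <- vector("list", n_channels(img))
  for (ci in seq_len(n_channels(img))) {
    ch <- get_channel(img, ci)
    if (length(dim(ch)) < 3L) dim(ch) <- c(nz, dim(img$intensities)[2:3])
    if (rolling_ball_radius_px >= 1L) {
      for (z in seq_len(nz)) {
        ch[z, , ] <- rolling_ball_background(ch[z, , ],
                                             rolling_ball_radius_px)
      }
    }
    if (!is.null(saturation_fraction)) {
      if (normalize_scope == "stack") {
        ch <- percentile_normalize(ch, saturation_fraction)
      } else {
        for (z in seq_len(nz)) {
          ch[z, , ] <- percentile_normalize(ch[z, , ], saturation_fraction)
        }
      }
    }
    if (projection == "max") {
      pl <- max_project(ch)
      if (blur_sigma_px > 0) pl <- gaussian_blur(pl, blur_sigma_px)
      ch <- array(pl, dim = c(1L, dim(pl)))
    }
    out[[ci]] <- ch
  }
  image_stack(out, img$voxel, img$channel_names)
}

#' Preprocess a set of sections with pooled normalization quantiles
#'
#' Background-subtracts each stack slice-wise, then computes the
#' normalization quantiles per channel across *all* stacks in the set
#' (the "section-set" scope: intensity normalization across the analyzed
#' sections of one animal) and applies the shared linear rescaling to
#' every stack.
#'
#' @param stacks list of [image_stack()] objects with identical channels.
#' @param rolling_ball_radius_px,saturation_fraction as in
#'   [preprocess_stack()].
#' @return list of preprocessed [image_stack()] objects.
#' @export
preprocess_section_set <- function(stacks, rolling_ball_radius_px = 6L,
                                   saturation_fraction = 0.02) {
  stopifnot(length(stacks) >= 1L,
            all(vapply(stacks, inherits, logical(1), "image_stack")))
  chs <- stacks[[1L]]$channel_names
  bg <- lapply(stacks, preprocess_stack,
               rolling_ball_radius_px = rolling_ball_radius_px,
               saturation_fraction = NULL)
  for (ci in seq_along(chs)) {
    pooled <- unlist(lapply(bg, function(s) as.vector(get_channel(s, ci))))
    q <- quantile(pooled, c(saturation_fraction / 2,
                            1 - saturation_fraction / 2), names = FALSE)
    for (si in seq_along(bg)) {
      ch <- bg[[si]]$intensities[, , , ci]
      if (q[2L] <= q[1L]) {
        warning("degenerate section set: quantiles coincide; returning zeros")
        ch[] <- 0
      } else {
        ch <- pmin(pmax((ch - q[1L]) / (q[2L] - q[1L]), 0), 1)
      }
      bg[[si]]$intensities[, , , ci] <- ch
    }
  }
  bg
}
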