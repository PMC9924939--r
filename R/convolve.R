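# Separable convolution with symmetric (reflective) boundary handling.
# All filtering in the package goes through these helpers so that the
# anisotropic-voxel bookkeeping lives in exactly one place.

# reflect an out-of-range 1-based index into [1, n] (symmetric: edge repeated)
reflect_index <- function(p, n) {
  if (n == 1L) return(rep.int(1L, length(p)))
  period <- 2L * n
  p <- ((p - 1L) %% period + period) %% period # 0 .. 2n-1
  ifelse(p < n, p + 1L, 2L * n - p)
}

# convolve array `a` along `axis` with an odd-length symmetric kernel `k`
conv_axis <- function(a, k, axis) {
  if (length(k) == 1L) return(a * k)
  d <- dim(a)
  if (is.null(d)) d <- length(a)
  n <- d[axis]
  half <- (length(k) - 1L) %/% 2L
  perm <- c(axis, seq_along(d)[-axis])
  m <- matrix(aperm(a, perm), nrow = n)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(k)) {
    rows <- reflect_index(seq_len(n) + (j - 1L - half), n)
    out <- out + k[j] * m[rows, , drop = FALSE]
  }
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

# normalized 1D Gaussian kernel sampled at integer offsets; sigma in voxels
gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- seq.int(-r, r)
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# smooth a 3D array (nz, ny, nx) with per-axis sigmas given in voxels
# sigma_vox is ordered (z, y, x) to match the array axes
smooth_gaussian_3d <- function(a, sigma_vox) {
  for (axis in 1:3) {
    if (sigma_vox[axis] > 0) {
      a <- conv_axis(a, gaussian_kernel_1d(sigma_vox[axis]), axis)
    }
  }
  a
}

# discrete second difference along an axis (approximates d^2/dvox^2),
# symmetric boundary
second_difference <- function(a, axis) {
  conv_axis(a, c(1, -2, 1), axis)
}
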