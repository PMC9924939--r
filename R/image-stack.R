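#' Physical voxel size
#'
#' Edge lengths of one voxel in micrometres. Anisotropy is allowed and is
#' the norm for confocal stacks (z-steps of 0.125 or 0.5 um against
#' ~0.1 um xy pixels), so all downstream geometry (distances, margins,
#' colocalization radii) is done in physical units, never in voxel indices.
#'
#' @param dx,dy,dz voxel edge lengths along x, y, z in micrometres;
#'   all strictly positive.
#' @return A named numeric vector of class `voxel_size`.
#' @examples
#' voxel_size(0.1, 0.1, 0.125)
#' @export
voxel_size <- function(dx, dy, dz) {
  v <- c(dx = as.numeric(dx), dy = as.numeric(dy), dz = as.numeric(dz))
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("voxel edge lengths must be finite and strictly positive")
  }
  structure(v, class = "voxel_size")
}

#' Volume of one voxel in cubic micrometres
#' @param voxel a [voxel_size()]
#' @return scalar um^3
#' @export
voxel_volume <- function(voxel) unname(prod(voxel))

#' Multi-channel 3D image stack with physical voxel size
#'
#' The container for all image data in the package: a non-negative
#' intensity grid indexed `[z, y, x, channel]` together with a
#' [voxel_size()] and ordered channel names. The physical extent along an
#' axis is `n * d` (a voxel with index `i`, 1-based, spans
#' `[(i-1)*d, i*d)` um and has its centre at `(i - 0.5) * d`).
#'
#' @param intensities a 3D array `(nz, ny, nx)` for a single channel, a 4D
#'   array `(nz, ny, nx, nchannel)`, or a list of congruent 3D arrays.
#' @param voxel a [voxel_size()].
#' @param channel_names character vector of channel labels (e.g.
#'   `c("Homer1", "Vglut1")`); defaults to `"ch1"`, `"ch2"`, ...
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(intensities, voxel, channel_names = NULL) {
  if (is.list(intensities)) {
    dims <- unique(lapply(intensities, dim))
    if (length(dims) != 1L) stop("all channels must have identical dimensions")
    intensities <- array(unlist(intensities, use.names = FALSE),
                         dim = c(dims[[1L]], length(intensities)))
  }
  if (length(dim(intensities)) == 3L) {
    dim(intensities) <- c(dim(intensities), 1L)
  }
  if (length(dim(intensities)) != 4L) {
    stop("intensities must be a 3D or 4D array, or a list of 3D arrays")
  }
  if (any(dim(intensities) < 1L)) stop("grid dimensions must all be >= 1")
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and non-negative")
  }
  stopifnot(inherits(voxel, "voxel_size"))
  nc <- dim(intensities)[4L]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc) {
    stop("channel_names length does not match the number of channels")
  }
  structure(list(intensities = intensities, voxel = voxel,
                 channel_names = as.character(channel_names)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("image_stack: %d x %d x %d voxels (z,y,x), %d channel(s)\n",
              d[1L], d[2L], d[3L], d[4L]))
  cat(sprintf("  voxel: %.4g x %.4g x %.4g um (dx,dy,dz)\n",
              x$voxel["dx"], x$voxel["dy"], x$voxel["dz"]))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Extract a channel as a 3D array
#' @param img an [image_stack()]
#' @param channel channel name or index
#' @return 3D array `(nz, ny, nx)`
#' @export
get_channel <- function(img, channel) {
  stopifnot(inherits(img, "image_stack"))
  if (is.character(channel)) {
    idx <- match(channel, img$channel_names)
    if (is.na(idx)) {
      stop(sprintf("channel '%s' not found (have: %s)", channel,
                   paste(img$channel_names, collapse = ", ")))
    }
    channel <- idx
  }
  img$intensities[, , , channel, drop = TRUE]
}

#' Number of channels in a stack
#' @param img an [image_stack()]
#' @export
n_channels <- function(img) dim(img$intensities)[4L]

#' Physical extent of a stack in micrometres
#'
#' Full extent `n * d` per axis, following the half-open voxel convention.
#'
#' @param img an [image_stack()]
#' @return named numeric `c(x=, y=, z=)` in um
#' @export
stack_extent <- function(img) {
  d <- dim(img$intensities)
  c(x = d[3L] * unname(img$voxel["dx"]),
    y = d[2L] * unname(img$voxel["dy"]),
    z = d[1L] * unname(img$voxel["dz"]))
}

# physical centre coordinates of voxel index vectors (1-based)
voxel_centers <- function(n, d) (seq_len(n) - 0.5) * d

# nearest voxel index for a physical coordinate, clamped to the grid
nearest_voxel <- function(pos, d, n) {
  pmin(pmax(as.integer(floor(pos / d)) + 1L, 1L), n)
}
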