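# TIFF + JSON-sidecar image I/O and puncta CSV I/O. Stacks are written
# as multi-page 32-bit float TIFFs (pages ordered z-within-channel) with
# intensities rescaled into [0, 1] by a factor recorded in the sidecar,
# which also carries the voxel size, grid dimensions and channel names.

#' Write an image stack to a multi-page TIFF with a JSON sidecar
#'
#' @param img an [image_stack()]
#' @param path output TIFF path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly
#' @export
write_image_stack <- function(img, path) {
  stopifnot(inherits(img, "image_stack"))
  d <- dim(img$intensities)
  scale <- max(img$intensities, 1e-12)
  pages <- list()
  for (ci in seq_len(d[4L])) {
    for (z in seq_len(d[1L])) {
      pages[[length(pages) + 1L]] <-
        img$intensities[z, , , ci] / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  side <- list(nz = d[1L], ny = d[2L], nx = d[3L], n_channels = d[4L],
               channel_names = img$channel_names,
               voxel = as.list(unclass(img$voxel)),
               intensity_scale = scale,
               page_order = "z_within_channel")
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#' @param path TIFF path (the `<path>.json` sidecar must exist).
#' @return an [image_stack()]
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path) || !file.exists(paste0(path, ".json"))) {
    stop(sprintf("image stack '%s' or its .json sidecar does not exist",
                 path))
  }
  side <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- side$nz
  nc <- side$n_channels
  if (length(pages) != nz * nc) {
    stop("TIFF page count does not match the sidecar dimensions")
  }
  arr <- array(0, dim = c(nz, side$ny, side$nx, nc))
  k <- 0L
  for (ci in seq_len(nc)) {
    for (z in seq_len(nz)) {
      k <- k + 1L
      arr[z, , , ci] <- pages[[k]] * side$intensity_scale
    }
  }
  image_stack(arr, voxel_size(side$voxel$dx, side$voxel$dy,
                              side$voxel$dz),
              channel_names = side$channel_names)
}

#' Write a puncta set to CSV
#'
#' Columns: `channel, x_um, y_um, z_um, raw_intensity, response,
#' n_merged`.
#'
#' @param ps a `puncta_set`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_puncta_csv <- function(ps, path) {
  stopifnot(inherits(ps, "puncta_set"))
  df <- data.frame(channel = rep(ps$channel, nrow(ps$puncta)),
                   x_um = ps$puncta$x, y_um = ps$puncta$y,
                   z_um = ps$puncta$z,
                   raw_intensity = ps$puncta$raw_intensity,
                   response = ps$puncta$response,
                   n_merged = ps$puncta$n_merged)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a puncta CSV back into a `puncta_set`
#' @param path CSV path
#' @param extent physical extent `c(x=, y=, z=)` um of the source image
#'   (stored in run manifests, not in the CSV itself).
#' @param params optional [detection_params()] echo.
#' @return a `puncta_set`
#' @export
read_puncta_csv <- function(path, extent, params = NULL) {
  df <- read.csv(path)
  ch <- if (nrow(df) > 0L) df$channel[1L] else NA_character_
  puncta <- data.frame(x = df$x_um, y = df$y_um, z = df$z_um,
                       response = df$response,
                       raw_intensity = df$raw_intensity,
                       n_merged = df$n_merged)
  new_puncta_set(puncta, ch, extent, params)
}
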