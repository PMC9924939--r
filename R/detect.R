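# Puncta detection: scale-matched LoG (3D tissue path) or DoG (2D culture
# path) filtering, full-neighbourhood local maxima, single-linkage merging
# within one punctum width, edge exclusion and a global Otsu intensity
# gate. All distances and margins are physical micrometres; filter sigmas
# are converted to voxels per axis, so anisotropic grids are handled
# correctly.

#' Detection parameters
#'
#' @param punctum_diameter_um expected punctum diameter in um (0.2 for
#'   tissue synaptic puncta; 0.72 for the culture DoG path).
#' @param mode `"log3d"` (scale-normalized Laplacian of Gaussian on the
#'   3D stack) or `"dog2d"` (difference of Gaussians on the
#'   max-intensity projection).
#' @param merge_radius_um candidates within this distance are merged into
#'   one punctum ("one punctum width"; default = the diameter).
#' @param edge_margin_um puncta closer than this to any physical face are
#'   excluded (default = half the diameter: the smallest margin at which
#'   a punctum's profile is fully sampled).
#' @param intensity_gate `"otsu"` (global 256-bin Otsu threshold on the
#'   channel's voxel intensities), a fixed numeric threshold, or
#'   `"none"`.
#' @param quality_threshold optional detector-response floor used instead
#'   of the intensity gate in `dog2d` mode; `NULL` defaults to an Otsu
#'   threshold on the response distribution.
#' @param sigma_um optional explicit filter scale in um; by default
#'   `diameter / (2 * sqrt(3))` for `log3d` (the scale-space optimum for
#'   a 3D ball of that diameter) and `diameter / (2 * sqrt(2))` for
#'   `dog2d`.
#' @return list of class `detection_params`
#' @export
detection_params <- function(punctum_diameter_um = 0.2,
                             mode = c("log3d", "dog2d"),
                             merge_radius_um = punctum_diameter_um,
                             edge_margin_um = punctum_diameter_um / 2,
                             intensity_gate = "otsu",
                             quality_threshold = NULL,
                             sigma_um = NULL) {
  mode <- match.arg(mode)
  stopifnot(punctum_diameter_um > 0, merge_radius_um >= 0,
            edge_margin_um >= 0)
  if (!(identical(intensity_gate, "otsu") ||
        identical(intensity_gate, "none") ||
        (is.numeric(intensity_gate) && length(intensity_gate) == 1L))) {
    stop("intensity_gate must be \"otsu\", \"none\", or a single number")
  }
  structure(list(punctum_diameter_um = punctum_diameter_um, mode = mode,
                 merge_radius_um = merge_radius_um,
                 edge_margin_um = edge_margin_um,
                 intensity_gate = intensity_gate,
                 quality_threshold = quality_threshold,
                 sigma_um = sigma_um),
            class = "detection_params")
}

#' Scale-normalized Laplacian-of-Gaussian response
#'
#' Smooths the channel with a Gaussian whose physical standard deviation
#' is `diameter / (2 * sqrt(3))` by default (the scale at which the 3D
#' LoG response to a ball of that diameter peaks), converted to per-axis
#' voxel sigmas, then applies the Laplacian in physical units and
#' multiplies by `-sigma^2` so that bright blobs of the matched size
#' produce positive response peaks.
#'
#' @param channel 3D array `(nz, ny, nx)`, finite.
#' @param voxel a [voxel_size()].
#' @param diameter_um expected blob diameter in um (> 0). A warning is
#'   issued when the diameter is under twice the smallest voxel edge
#'   (the blob is then badly undersampled).
#' @param sigma_um optional explicit filter sd in um.
#' @return response array of the same shape.
#' @export
log_response <- function(channel, voxel, diameter_um, sigma_um = NULL) {
  stopifnot(length(dim(channel)) == 3L, inherits(voxel, "voxel_size"))
  if (!is.numeric(diameter_um) || diameter_um <= 0) {
    stop("diameter_um must be positive")
  }
  if (diameter_um < 2 * min(voxel)) {
    warning("blob diameter is below twice the smallest voxel edge; ",
            "the filter scale is undersampled")
  }
  if (is.null(sigma_um)) sigma_um <- diameter_um / (2 * sqrt(3))
  d_axis <- unname(voxel[c("dz", "dy", "dx")]) # array axis order
  smoothed <- smooth_gaussian_3d(channel, sigma_um / d_axis)
  resp <- array(0, dim = dim(channel))
  for (axis in 1:3) {
    resp <- resp + second_difference(smoothed, axis) / d_axis[axis]^2
  }
  -sigma_um^2 * resp
}

#' Difference-of-Gaussians response (2D)
#'
#' Band-pass blob filter for the projected culture images: the narrow
#' minus the wide Gaussian smoothing, with `sigma1 = sigma_phys /
#' sqrt(1.6)`, `sigma2 = 1.6 * sigma1` and `sigma_phys = diameter /
#' (2 * sqrt(2))`, so their geometric mean matches the blob scale.
#' Bright blobs give positive peaks.
#'
#' @param plane 2D matrix.
#' @param voxel a [voxel_size()] (only `dx`, `dy` are used).
#' @param diameter_um expected blob diameter in um.
#' @param sigma_um optional explicit centre scale in um.
#' @return response matrix.
#' @export
dog_response <- function(plane, voxel, diameter_um, sigma_um = NULL) {
  stopifnot(is.matrix(plane), inherits(voxel, "voxel_size"),
            diameter_um > 0)
  if (is.null(sigma_um)) sigma_um <- diameter_um / (2 * sqrt(2))
  s1 <- sigma_um / sqrt(1.6)
  s2 <- 1.6 * s1
  d_axis <- unname(voxel[c("dy", "dx")])
  blur2d <- function(p, s_um) {
    conv_axis(conv_axis(p, gaussian_kernel_1d(s_um / d_axis[1L]), 1L),
              gaussian_kernel_1d(s_um / d_axis[2L]), 2L)
  }
  blur2d(plane, s1) - blur2d(plane, s2)
}

#' Local maxima of a response grid (full neighbourhood)
#'
#' Returns every voxel whose response is greater than or equal to all of
#' its 26 neighbours (8 for single-slice grids; borders compare only
#' their existing neighbours). A connected plateau of equal-valued
#' maxima yields a single candidate at the plateau centroid, which keeps
#' the candidate set deterministic.
#'
#' @param response 3D array `(nz, ny, nx)`; finite.
#' @param voxel a [voxel_size()].
#' @param raw optional congruent array of raw intensities from which each
#'   candidate's `raw_intensity` is read (at the voxel nearest its
#'   centroid); defaults to the response itself.
#' @return data.frame with columns `x, y, z` (um), `response`,
#'   `raw_intensity`, `n_voxels` (plateau size).
#' @export
find_local_maxima <- function(response, voxel, raw = NULL) {
  stopifnot(length(dim(response)) == 3L, all(is.finite(response)))
  if (is.null(raw)) raw <- response
  dm <- dim(response)
  nz <- dm[1L]; ny <- dm[2L]; nx <- dm[3L]
  pad <- array(-Inf, dim = dm + 2L)
  pad[2:(nz + 1L), 2:(ny + 1L), 2:(nx + 1L)] <- response
  mask <- array(TRUE, dim = dm)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0L && dy == 0L && dx == 0L) next
    nb <- pad[(1:nz) + 1L + dz, (1:ny) + 1L + dy, (1:nx) + 1L + dx,
              drop = FALSE]
    dim(nb) <- dm
    mask <- mask & (response >= nb)
  }
  labels <- .label_cc3d(as.vector(mask), dm)
  idx <- which(mask)
  if (length(idx) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      response = numeric(0), raw_intensity = numeric(0),
                      n_voxels = integer(0)))
  }
  lab <- labels[idx]
  ai <- arrayInd(idx, dm) # columns: z, y, x indices
  cz <- rowsum((ai[, 1L] - 0.5) * unname(voxel["dz"]), lab)
  cy <- rowsum((ai[, 2L] - 0.5) * unname(voxel["dy"]), lab)
  cx <- rowsum((ai[, 3L] - 0.5) * unname(voxel["dx"]), lab)
  cnt <- as.vector(rowsum(rep(1L, length(lab)), lab))
  pos <- cbind(x = as.vector(cx) / cnt, y = as.vector(cy) / cnt,
               z = as.vector(cz) / cnt)
  # plateau members share one response value; take it from the first
  first <- idx[!duplicated(lab)]
  ord <- order(unique(lab))
  resp_val <- response[first][ord]
  nzv <- nearest_voxel(pos[, "z"], unname(voxel["dz"]), nz)
  nyv <- nearest_voxel(pos[, "y"], unname(voxel["dy"]), ny)
  nxv <- nearest_voxel(pos[, "x"], unname(voxel["dx"]), nx)
  raw_val <- raw[cbind(nzv, nyv, nxv)]
  data.frame(x = pos[, "x"], y = pos[, "y"], z = pos[, "z"],
             response = resp_val, raw_intensity = raw_val,
             n_voxels = cnt)
}

# minimal union-find (path halving)
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges) > 0L) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1L])
      b <- find(edges[k, 2L])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Merge candidate maxima within one punctum width
#'
#' Links candidates closer than `merge_radius_um` (physical distance,
#' link at `d <= r`) and takes single-linkage connected components; each
#' component becomes one punctum at its response-weighted centroid with
#' `response` = component maximum, `raw_intensity` from the
#' maximal-response member, and `n_merged` = component size. Members are
#' processed in a canonical coordinate order, so the output is invariant
#' to the input permutation.
#'
#' @param candidates data.frame as from [find_local_maxima()].
#' @param merge_radius_um merge radius in um (>= 0).
#' @return data.frame with columns `x, y, z, response, raw_intensity,
#'   n_merged`.
#' @export
merge_candidates <- function(candidates, merge_radius_um) {
  stopifnot(merge_radius_um >= 0)
  n <- nrow(candidates)
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      response = numeric(0), raw_intensity = numeric(0),
                      n_merged = integer(0))
  if (n == 0L) return(empty)
  ord <- order(candidates$x, candidates$y, candidates$z)
  cand <- candidates[ord, , drop = FALSE]
  coords <- cbind(cand$x, cand$y, cand$z)
  comp <- if (merge_radius_um == 0 || n == 1L) {
    seq_len(n)
  } else {
    uf_components(n, .pairs_within_radius(coords, merge_radius_um))
  }
  w <- cand$response
  sizes <- tabulate(comp)
  single <- sizes[comp] == 1L
  res_single <- data.frame(x = cand$x[single], y = cand$y[single],
                           z = cand$z[single], response = w[single],
                           raw_intensity = cand$raw_intensity[single],
                           n_merged = rep(1L, sum(single)))
  idx_multi <- which(!single)
  res_multi <- NULL
  if (length(idx_multi) > 0L) {
    spl <- split(idx_multi, comp[idx_multi])
    k <- length(spl)
    mx <- my <- mz <- mresp <- mraw <- numeric(k)
    msize <- integer(k)
    for (g in seq_len(k)) {
      ix <- spl[[g]]
      wi <- w[ix]
      # response weights can be non-positive for candidates in dim
      # regions; shift so the weighted centroid stays well defined
      if (any(wi <= 0)) wi <- wi - min(wi) + 1e-12
      wi <- wi / sum(wi)
      best <- ix[which.max(w[ix])]
      mx[g] <- sum(coords[ix, 1L] * wi)
      my[g] <- sum(coords[ix, 2L] * wi)
      mz[g] <- sum(coords[ix, 3L] * wi)
      mresp[g] <- max(w[ix])
      mraw[g] <- cand$raw_intensity[best]
      msize[g] <- length(ix)
    }
    res_multi <- data.frame(x = mx, y = my, z = mz, response = mresp,
                            raw_intensity = mraw, n_merged = msize)
  }
  res <- rbind(res_single, res_multi)
  res <- res[order(res$x, res$y, res$z), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Global Otsu threshold over a 256-bin histogram
#'
#' The threshold maximizing between-class variance over a 256-bin
#' histogram spanning the sample range; ties are broken toward the lower
#' threshold. The returned value is the boundary between the two bin
#' classes.
#'
#' @param values numeric sample (at least two distinct values).
#' @param n_bins number of histogram bins (default 256).
#' @return scalar threshold.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  r <- range(values)
  if (length(values) < 2L || r[1L] == r[2L]) {
    stop("degenerate histogram: need at least two distinct values")
  }
  width <- (r[2L] - r[1L]) / n_bins
  bin <- pmin(floor((values - r[1L]) / width) + 1L, n_bins)
  counts <- as.numeric(tabulate(bin, n_bins))
  mids <- r[1L] + (seq_len(n_bins) - 0.5) * width
  w0 <- cumsum(counts)[-n_bins]
  w1 <- sum(counts) - w0
  s0 <- cumsum(counts * mids)[-n_bins]
  mu0 <- ifelse(w0 > 0, s0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (sum(counts * mids) - s0) / w1, 0)
  between <- w0 * w1 * (mu0 - mu1)^2
  k <- which.max(between) # first maximum = lowest threshold on ties
  r[1L] + k * width
}

#' Edge and intensity filtering of merged puncta
#'
#' Removes puncta whose centre lies within `edge_margin_um` of any
#' physical image face, then removes puncta whose `raw_intensity` is
#' below `gate_threshold` (both filters are pointwise, so their order is
#' immaterial).
#'
#' @param puncta data.frame from [merge_candidates()].
#' @param extent physical extent, named `c(x=, y=, z=)` um.
#' @param edge_margin_um margin in um; scalar or per-axis `c(x, y, z)`.
#' @param gate_threshold numeric threshold or `NULL` for no intensity
#'   gate.
#' @param gate_on which column the gate applies to (`"raw_intensity"` or
#'   `"response"`).
#' @return filtered data.frame.
#' @export
filter_candidates <- function(puncta, extent, edge_margin_um,
                              gate_threshold = NULL,
                              gate_on = "raw_intensity") {
  m <- rep_len(edge_margin_um, 3L)
  keep <- puncta$x >= m[1L] & puncta$x <= extent[["x"]] - m[1L] &
    puncta$y >= m[2L] & puncta$y <= extent[["y"]] - m[2L] &
    puncta$z >= m[3L] & puncta$z <= extent[["z"]] - m[3L]
  if (!is.null(gate_threshold)) {
    keep <- keep & puncta[[gate_on]] >= gate_threshold
  }
  out <- puncta[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_puncta_set <- function(puncta, channel_name, extent, params,
                           gate_value = NA_real_) {
  structure(list(puncta = puncta, channel = channel_name, extent = extent,
                 params = params, gate_value = gate_value),
            class = "puncta_set")
}

#' @export
print.puncta_set <- function(x, ...) {
  cat(sprintf("puncta_set: %d puncta in channel '%s' (%.3g x %.3g x %.3g um)\n",
              nrow(x$puncta), x$channel, x$extent[["x"]], x$extent[["y"]],
              x$extent[["z"]]))
  invisible(x)
}

#' Number of puncta in a set
#' @param ps a `puncta_set`
#' @export
n_puncta <- function(ps) nrow(ps$puncta)

#' Coordinates of a puncta set as a matrix
#' @param ps a `puncta_set` (or a data.frame/matrix with x, y, z)
#' @return n x 3 matrix with columns x, y, z (um)
#' @export
puncta_coords <- function(ps) {
  df <- if (inherits(ps, "puncta_set")) ps$puncta else ps
  m <- cbind(x = df[, "x"], y = df[, "y"], z = df[, "z"])
  rownames(m) <- NULL
  m
}

#' Detect puncta in one channel of an image stack
#'
#' The full detection composition. In `log3d` mode: scale-normalized LoG
#' response, full-neighbourhood local maxima, single-linkage merging
#' within one punctum width, edge exclusion, and a global Otsu intensity
#' gate computed over the whole channel. In `dog2d` mode the channel is
#' first max-projected, a difference-of-Gaussians response is used, and
#' the gate is the configured `quality_threshold` on the detector
#' response (defaulting to an Otsu threshold on the response
#' distribution).
#'
#' @param img an [image_stack()]
#' @param channel channel name or index.
#' @param params a [detection_params()]
#' @return a `puncta_set`
#' @export
detect_puncta <- function(img, channel, params = detection_params()) {
  stopifnot(inherits(img, "image_stack"),
            inherits(params, "detection_params"))
  ch <- get_channel(img, channel)
  if (length(dim(ch)) < 3L) {
    dim(ch) <- c(1L, dim(ch)) # single-slice stack
  }
  ch_name <- if (is.character(channel)) channel else
    img$channel_names[channel]
  voxel <- img$voxel
  extent <- stack_extent(img)
  if (min(ch) == max(ch)) {
    # blank channel: nothing to detect (and no meaningful Otsu gate)
    empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                        response = numeric(0), raw_intensity = numeric(0),
                        n_merged = integer(0))
    return(new_puncta_set(empty, ch_name, extent, params))
  }

  if (params$mode == "log3d") {
    resp <- log_response(ch, voxel, params$punctum_diameter_um,
                         params$sigma_um)
    cands <- find_local_maxima(resp, voxel, raw = ch)
    merged <- merge_candidates(cands, params$merge_radius_um)
    # refresh raw intensity at each merged punctum's nearest voxel
    if (nrow(merged) > 0L) {
      dm <- dim(ch)
      merged$raw_intensity <- ch[cbind(
        nearest_voxel(merged$z, unname(voxel["dz"]), dm[1L]),
        nearest_voxel(merged$y, unname(voxel["dy"]), dm[2L]),
        nearest_voxel(merged$x, unname(voxel["dx"]), dm[3L]))]
    }
    gate <- if (identical(params$intensity_gate, "otsu")) {
      otsu_threshold(as.vector(ch))
    } else if (is.numeric(params$intensity_gate)) {
      params$intensity_gate
    } else NULL
    out <- filter_candidates(merged, extent, params$edge_margin_um, gate,
                             gate_on = "raw_intensity")
    return(new_puncta_set(out, ch_name, extent, params,
                          if (is.null(gate)) NA_real_ else gate))
  }

  # dog2d: max-project, filter in 2D, gate on the detector response
  proj <- max_project(ch)
  resp2 <- dog_response(proj, voxel, params$punctum_diameter_um,
                        params$sigma_um)
  resp3 <- array(resp2, dim = c(1L, dim(resp2)))
  raw3 <- array(proj, dim = c(1L, dim(proj)))
  cands <- find_local_maxima(resp3, voxel, raw = raw3)
  merged <- merge_candidates(cands, params$merge_radius_um)
  gate <- if (!is.null(params$quality_threshold)) {
    params$quality_threshold
  } else {
    otsu_threshold(as.vector(resp2))
  }
  extent2 <- extent
  extent2[["z"]] <- unname(voxel["dz"]) # projected: one slice deep
  out <- filter_candidates(merged, extent2,
                           c(params$edge_margin_um,
                             params$edge_margin_um, 0),
                           gate, gate_on = "response")
  new_puncta_set(out, ch_name, extent2, params, gate)
}
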