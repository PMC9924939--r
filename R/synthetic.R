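# Synthetic phantom generation with exact ground truth.
#
# Two phantom families are produced: two-channel puncta fields emulating
# confocal z-stacks of pre-/post-synaptic markers, and three-channel
# nested-solid phantoms emulating microglia (cell / lysosome / engulfed
# cargo). Every simulated object is recorded in a ground-truth structure
# so detection, colocalization, density and volumetric stages can all be
# validated against known answers.

#' Round half away from zero at .5 (deterministic "half up" rule)
#' @param x numeric
#' @return integer-valued numeric
#' @export
round_half_up <- function(x) floor(x + 0.5)

#' Parameters for a two-channel synaptic puncta field
#'
#' Defaults describe the standard recovery phantom: a 256 x 256 x 16 voxel
#' grid at 0.1 x 0.1 x 0.125 um (25.6 x 25.6 x 2 um, the 2-um z-stack
#' geometry typical of synaptic confocal imaging), 150 puncta per channel
#' of 0.2 um FWHM, 40% of reference (post-synaptic) puncta paired with a
#' target (pre-synaptic) punctum displaced by less than 0.15 um so that
#' true pairs sit strictly inside the 0.2 um colocalization radius.
#'
#' @param shape integer grid dimensions `c(nz, ny, nx)`.
#' @param voxel a [voxel_size()].
#' @param n_reference,n_target puncta counts for the reference
#'   (channel 2, post-synaptic) and target (channel 3, pre-synaptic)
#'   channels.
#' @param coloc_fraction fraction of reference puncta given a paired
#'   target punctum, in `[0, 1]`. The number of pairs is
#'   `round_half_up(n_reference * coloc_fraction)`; a warning is issued
#'   when the product is not an integer.
#' @param pair_offset_max maximum pairing displacement in um (offsets are
#'   drawn uniformly in a ball of this radius).
#' @param punctum_fwhm full width at half maximum of each punctum's
#'   Gaussian intensity profile, um (isotropic in physical space).
#' @param amplitude_mean,amplitude_cv mean and coefficient of variation of
#'   punctum peak brightness (normal, truncated just above zero).
#' @param background_level additive baseline intensity.
#' @param shot_noise logical; apply Poisson noise to signal + background.
#' @param gain intensity units per photon count for the Poisson stage.
#' @param read_noise_sd standard deviation of additive Gaussian read
#'   noise (intensity units).
#' @param min_separation um; minimum distance enforced between
#'   same-channel puncta and between non-paired cross-channel puncta.
#'   Keeping this above the colocalization radius guarantees that the
#'   ground-truth colocalized fraction equals `coloc_fraction` exactly.
#' @param edge_margin um; puncta are placed at least this far from every
#'   physical face (default one FWHM) so a detector's edge exclusion
#'   cannot remove true positives.
#' @param channel_names labels for (reference, target).
#' @param seed RNG seed (`NULL` = use the current RNG state).
#' @return a list of class `puncta_field_params`
#' @export
puncta_field_params <- function(shape = c(16L, 256L, 256L),
                                voxel = voxel_size(0.1, 0.1, 0.125),
                                n_reference = 150L,
                                n_target = 150L,
                                coloc_fraction = 0.4,
                                pair_offset_max = 0.15,
                                punctum_fwhm = 0.2,
                                amplitude_mean = 150,
                                amplitude_cv = 0.15,
                                background_level = 3,
                                shot_noise = TRUE,
                                gain = 1,
                                read_noise_sd = 0,
                                min_separation = 0.3,
                                edge_margin = punctum_fwhm,
                                channel_names = c("Homer1", "Vglut1"),
                                seed = NULL) {
  p <- list(shape = as.integer(shape), voxel = voxel,
            n_reference = as.integer(n_reference),
            n_target = as.integer(n_target),
            coloc_fraction = coloc_fraction,
            pair_offset_max = pair_offset_max,
            punctum_fwhm = punctum_fwhm,
            amplitude_mean = amplitude_mean, amplitude_cv = amplitude_cv,
            background_level = background_level,
            shot_noise = isTRUE(shot_noise), gain = gain,
            read_noise_sd = read_noise_sd,
            min_separation = min_separation,
            edge_margin = edge_margin,
            channel_names = channel_names, seed = seed)
  stopifnot(length(p$shape) == 3L, all(p$shape >= 1L),
            p$n_reference >= 0L, p$n_target >= 0L,
            p$coloc_fraction >= 0, p$coloc_fraction <= 1,
            p$pair_offset_max >= 0, p$punctum_fwhm > 0,
            p$min_separation >= 0, p$edge_margin >= 0)
  n_pairs <- p$n_reference * p$coloc_fraction
  if (abs(n_pairs - round_half_up(n_pairs)) > 1e-9) {
    warning(sprintf(
      "n_reference * coloc_fraction = %.3f is not an integer; using %d pairs",
      n_pairs, round_half_up(n_pairs)))
  }
  if (round_half_up(n_pairs) > p$n_target) {
    stop("coloc_fraction requires more pairs than n_target provides")
  }
  class(p) <- "puncta_field_params"
  p
}

# rejection-sample `n` points in the box [lower, upper]^3 (um) keeping
# every accepted point >= min_sep from `keepout` rows and from each other
place_points <- function(n, lower, upper, min_sep, keepout = NULL,
                         max_tries = 5000L) {
  pts <- matrix(numeric(0), ncol = 3,
                dimnames = list(NULL, c("x", "y", "z")))
  if (n == 0L) return(pts)
  if (any(upper <= lower)) {
    stop("placement domain is empty: grid too small for the edge margin")
  }
  all_pts <- rbind(keepout, pts)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- lower + runif(3) * (upper - lower)
      if (nrow(all_pts) == 0L ||
          min(rowSums(sweep(all_pts, 2, cand)^2)) >= min_sep^2) {
        pts <- rbind(pts, cand)
        all_pts <- rbind(all_pts, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(paste0(
        "failed to place point %d of %d: density too high for ",
        "min_separation = %.3g um in a %.3g x %.3g x %.3g um domain"),
        i, n, min_sep, upper[1] - lower[1], upper[2] - lower[2],
        upper[3] - lower[3]))
    }
  }
  rownames(pts) <- NULL
  pts
}

# render isotropic-in-physical-space Gaussian puncta onto the (nz,ny,nx)
# grid by midpoint (voxel-centre) evaluation
render_puncta <- function(shape, voxel, positions, amplitudes, sigma_um) {
  img <- array(0, dim = shape)
  if (nrow(positions) == 0L) return(img)
  d <- c(x = unname(voxel["dx"]), y = unname(voxel["dy"]),
         z = unname(voxel["dz"]))
  nz <- shape[1L]; ny <- shape[2L]; nx <- shape[3L]
  reach <- 4 * sigma_um
  for (i in seq_len(nrow(positions))) {
    p <- positions[i, ]
    ix <- max(1L, floor((p["x"] - reach) / d["x"]) + 1L):
          min(nx, ceiling((p["x"] + reach) / d["x"]))
    iy <- max(1L, floor((p["y"] - reach) / d["y"]) + 1L):
          min(ny, ceiling((p["y"] + reach) / d["y"]))
    iz <- max(1L, floor((p["z"] - reach) / d["z"]) + 1L):
          min(nz, ceiling((p["z"] + reach) / d["z"]))
    wx <- exp(-((ix - 0.5) * d["x"] - p["x"])^2 / (2 * sigma_um^2))
    wy <- exp(-((iy - 0.5) * d["y"] - p["y"])^2 / (2 * sigma_um^2))
    wz <- exp(-((iz - 0.5) * d["z"] - p["z"])^2 / (2 * sigma_um^2))
    img[iz, iy, ix] <- img[iz, iy, ix] + amplitudes[i] * (wz %o% wy %o% wx)
  }
  img
}

# fluorescence noise model: Poisson shot noise on (signal + background)
# in counts of size `gain`, then Gaussian read noise, then clipping at 0
apply_noise <- function(img, shot_noise, gain, read_noise_sd) {
  if (shot_noise) {
    img[] <- rpois(length(img), pmax(img, 0) / gain) * gain
  }
  if (read_noise_sd > 0) {
    img[] <- img + rnorm(length(img), sd = read_noise_sd)
  }
  pmax(img, 0)
}

new_ground_truth <- function(positions, pairs, phantom_volumes, params) {
  structure(list(positions = positions, pairs = pairs,
                 phantom_volumes = phantom_volumes, params = params),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:\n")
  for (ch in names(x$positions)) {
    cat(sprintf("  %s: %d true positions\n", ch, nrow(x$positions[[ch]])))
  }
  cat(sprintf("  pairs: %d\n",
              if (is.null(x$pairs)) 0L else nrow(x$pairs)))
  if (!is.null(x$phantom_volumes)) {
    cat("  phantom volumes (um^3):",
        paste(sprintf("%s=%.4g", names(x$phantom_volumes),
                      x$phantom_volumes), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Generate a two-channel synaptic puncta field with ground truth
#'
#' Places reference (post-synaptic) and target (pre-synaptic) puncta in
#' physical coordinates by rejection sampling, pairing a
#' `coloc_fraction` of reference puncta with a target punctum displaced
#' uniformly within a ball of radius `pair_offset_max`. Paired targets
#' are additionally kept `min_separation` away from every reference
#' punctum other than their partner, so the true colocalized fraction is
#' exactly the requested one whenever `min_separation` exceeds the
#' colocalization radius. Each punctum is rendered as an isotropic 3D
#' Gaussian of the stated FWHM sampled at voxel centres on the
#' (possibly anisotropic) grid, on top of a constant background, with
#' optional Poisson shot noise and Gaussian read noise.
#'
#' @param params a [puncta_field_params()]
#' @return list with elements `image` ([image_stack()], 2 channels) and
#'   `truth` (`ground_truth`: per-channel true positions in um, the pair
#'   index table, and a parameter echo).
#' @examples
#' fp <- puncta_field_params(shape = c(8, 64, 64), n_reference = 10,
#'                           n_target = 10, coloc_fraction = 0.5, seed = 1)
#' field <- generate_puncta_field(fp)
#' nrow(field$truth$pairs) # 5
#' @export
generate_puncta_field <- function(params) {
  stopifnot(inherits(params, "puncta_field_params"))
  gen <- function() {
    d <- params$voxel
    extent <- c(x = params$shape[3L] * unname(d["dx"]),
                y = params$shape[2L] * unname(d["dy"]),
                z = params$shape[1L] * unname(d["dz"]))
    lower <- rep(params$edge_margin, 3)
    upper <- unname(extent) - params$edge_margin
    n_pairs <- as.integer(round_half_up(
      params$n_reference * params$coloc_fraction))

    ref <- place_points(params$n_reference, lower, upper,
                        params$min_separation)
    paired_idx <- if (n_pairs > 0L) {
      sort(sample.int(params$n_reference, n_pairs))
    } else integer(0)

    # paired targets: inside the offset ball of their partner, inside the
    # placement domain, >= min_separation from other targets and from
    # every reference punctum except the partner
    tgt <- matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("x", "y", "z")))
    for (ri in paired_idx) {
      ok <- FALSE
      for (try in seq_len(5000L)) {
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        off <- u * params$pair_offset_max * runif(1)^(1 / 3)
        cand <- ref[ri, ] + off
        if (any(cand < lower) || any(cand > upper)) next
        other_ref <- ref[-ri, , drop = FALSE]
        if (nrow(other_ref) > 0L &&
            min(rowSums(sweep(other_ref, 2, cand)^2)) <
              params$min_separation^2) next
        if (nrow(tgt) > 0L &&
            min(rowSums(sweep(tgt, 2, cand)^2)) <
              params$min_separation^2) next
        tgt <- rbind(tgt, cand)
        ok <- TRUE
        break
      }
      if (!ok) {
        stop(paste0("failed to place a paired target punctum: ",
                    "min_separation too large for pair_offset_max"))
      }
    }
    # unpaired targets: away from all targets and all reference puncta
    n_unpaired <- params$n_target - n_pairs
    unpaired <- place_points(n_unpaired, lower, upper,
                             params$min_separation, keepout = rbind(ref, tgt))
    tgt <- rbind(tgt, unpaired)
    rownames(tgt) <- NULL
    pairs <- data.frame(reference = paired_idx,
                        target = seq_len(n_pairs))

    sigma <- params$punctum_fwhm / (2 * sqrt(2 * log(2)))
    amp <- function(n) {
      pmax(rnorm(n, params$amplitude_mean,
                 params$amplitude_cv * params$amplitude_mean),
           0.05 * params$amplitude_mean)
    }
    ch_ref <- render_puncta(params$shape, d, ref, amp(nrow(ref)), sigma) +
      params$background_level
    ch_tgt <- render_puncta(params$shape, d, tgt, amp(nrow(tgt)), sigma) +
      params$background_level
    ch_ref <- apply_noise(ch_ref, params$shot_noise, params$gain,
                          params$read_noise_sd)
    ch_tgt <- apply_noise(ch_tgt, params$shot_noise, params$gain,
                          params$read_noise_sd)

    img <- image_stack(list(ch_ref, ch_tgt), d,
                       channel_names = params$channel_names)
    pos <- list(ref, tgt)
    names(pos) <- params$channel_names
    truth <- new_ground_truth(pos, pairs, NULL, params)
    list(image = img, truth = truth)
  }
  if (is.null(params$seed)) gen() else withr::with_seed(params$seed, gen())
}

#' Parameters for a three-channel engulfment phantom
#'
#' Nested solids emulating a microglial cell (e.g. Iba1), a lysosomal
#' compartment inside it (CD68), and synaptic cargo inside the lysosome
#' (Vglut1). Radii may be scalars (spheres) or length-3 semi-axes
#' `(ax, ay, az)` um (axis-aligned ellipsoids). The nesting
#' cargo <= lysosome <= cell must hold as geometric solids.
#'
#' @param shape grid `c(nz, ny, nx)`; default 70^3.
#' @param voxel a [voxel_size()]; default 0.1 um isotropic.
#' @param cell,lysosome,cargo lists with `center` (um, `c(x, y, z)`;
#'   `NULL` = grid centre) and `radius` (um, scalar or length 3). A zero
#'   radius gives a blank compartment with volume 0.
#' @param intensities named numeric: painted intensity per compartment.
#' @param background_level additive baseline.
#' @param shot_noise,gain,read_noise_sd noise model as in
#'   [puncta_field_params()]; shot noise off by default here.
#' @param channel_names labels for (cell, lysosome, cargo).
#' @param seed RNG seed.
#' @return list of class `engulfment_phantom_params`
#' @export
engulfment_phantom_params <- function(shape = c(70L, 70L, 70L),
                                      voxel = voxel_size(0.1, 0.1, 0.1),
                                      cell = list(center = NULL, radius = 3),
                                      lysosome = list(center = NULL,
                                                      radius = 1.5),
                                      cargo = list(center = NULL,
                                                   radius = 0.5),
                                      intensities = c(cell = 120,
                                                      lysosome = 160,
                                                      cargo = 200),
                                      background_level = 10,
                                      shot_noise = FALSE,
                                      gain = 1,
                                      read_noise_sd = 5,
                                      channel_names = c("Iba1", "CD68",
                                                        "Vglut1"),
                                      seed = NULL) {
  p <- list(shape = as.integer(shape), voxel = voxel, cell = cell,
            lysosome = lysosome, cargo = cargo, intensities = intensities,
            background_level = background_level,
            shot_noise = isTRUE(shot_noise), gain = gain,
            read_noise_sd = read_noise_sd, channel_names = channel_names,
            seed = seed)
  class(p) <- "engulfment_phantom_params"
  p
}

# normalize a compartment spec to (center um, semi-axes um); radius 0 ok
resolve_solid <- function(spec, extent) {
  r <- spec$radius
  if (length(r) == 1L) r <- rep(r, 3L)
  if (length(r) != 3L || any(r < 0)) {
    stop("compartment radius must be a non-negative scalar or length-3")
  }
  ctr <- spec$center
  if (is.null(ctr)) ctr <- extent / 2
  list(center = unname(ctr), semi = unname(r))
}

# conservative ellipsoid nesting check: inner fits in outer if the centre
# offset plus the largest inner semi-axis stays inside the smallest outer
# semi-axis (exact for concentric spheres)
check_nested <- function(inner, outer, inner_name, outer_name) {
  if (all(inner$semi == 0)) return(invisible(TRUE))
  off <- sqrt(sum((inner$center - outer$center)^2))
  if (off + max(inner$semi) > min(outer$semi) + 1e-9) {
    stop(sprintf("%s is not nested inside %s", inner_name, outer_name))
  }
  invisible(TRUE)
}

ellipsoid_volume <- function(semi) 4 / 3 * pi * prod(semi)

# paint a filled ellipsoid: voxel centres with normalized distance <= 1
paint_solid <- function(shape, voxel, solid, value) {
  img <- array(0, dim = shape)
  if (any(solid$semi == 0)) return(img)
  zc <- voxel_centers(shape[1L], voxel["dz"])
  yc <- voxel_centers(shape[2L], voxel["dy"])
  xc <- voxel_centers(shape[3L], voxel["dx"])
  q <- outer(outer((zc - solid$center[3])^2 / solid$semi[3]^2,
                   (yc - solid$center[2])^2 / solid$semi[2]^2, "+"),
             (xc - solid$center[1])^2 / solid$semi[1]^2, "+")
  img[q <= 1] <- value
  img
}

#' Generate a nested-solid engulfment phantom with analytic ground truth
#'
#' Paints the cell, lysosome and cargo compartments as filled spheres or
#' ellipsoids into three channels at the stated intensities, adds
#' background and noise, and records the analytic volume
#' \eqn{(4/3)\pi r^3} (or the ellipsoid analogue) of each compartment.
#'
#' @param params an [engulfment_phantom_params()]
#' @return list with `image` (3-channel [image_stack()]) and `truth`
#'   (`ground_truth` whose `phantom_volumes` holds the analytic um^3 per
#'   compartment).
#' @export
generate_engulfment_phantom <- function(params) {
  stopifnot(inherits(params, "engulfment_phantom_params"))
  gen <- function() {
    d <- params$voxel
    extent <- c(params$shape[3L] * unname(d["dx"]),
                params$shape[2L] * unname(d["dy"]),
                params$shape[1L] * unname(d["dz"]))
    cell <- resolve_solid(params$cell, extent)
    lyso <- resolve_solid(params$lysosome, extent)
    cargo <- resolve_solid(params$cargo, extent)
    check_nested(lyso, cell, "lysosome", "cell")
    check_nested(cargo, lyso, "cargo", "lysosome")
    if (any(cell$center - cell$semi < -1e-9) ||
        any(cell$center + cell$semi > extent + 1e-9)) {
      stop("cell geometry escapes the image grid")
    }
    chans <- list(
      paint_solid(params$shape, d, cell, params$intensities[["cell"]]),
      paint_solid(params$shape, d, lyso, params$intensities[["lysosome"]]),
      paint_solid(params$shape, d, cargo, params$intensities[["cargo"]]))
    chans <- lapply(chans, function(ch) {
      apply_noise(ch + params$background_level, params$shot_noise,
                  params$gain, params$read_noise_sd)
    })
    img <- image_stack(chans, d, channel_names = params$channel_names)
    vols <- c(cell = ellipsoid_volume(cell$semi),
              lysosome = ellipsoid_volume(lyso$semi),
              cargo = ellipsoid_volume(cargo$semi))
    truth <- new_ground_truth(
      positions = stats::setNames(
        rep(list(matrix(numeric(0), ncol = 3,
                        dimnames = list(NULL, c("x", "y", "z")))), 3L),
        params$channel_names),
      pairs = NULL, phantom_volumes = vols, params = params)
    list(image = img, truth = truth)
  }
  if (is.null(params$seed)) gen() else withr::with_seed(params$seed, gen())
}

#' Write ground truth to a CSV with a JSON parameter sidecar
#'
#' One row per true punctum (`channel, index, x, y, z, pair_id`), with
#' paired puncta across channels sharing a `pair_id`. Parameters and any
#' analytic phantom volumes go into `<path>.json`. The coordinate set
#' round-trips losslessly through [read_ground_truth()].
#'
#' @param gt a `ground_truth`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  rows <- list()
  chs <- names(gt$positions)
  for (ci in seq_along(chs)) {
    pos <- gt$positions[[ci]]
    if (nrow(pos) == 0L) next
    pair_id <- rep(NA_integer_, nrow(pos))
    if (!is.null(gt$pairs) && nrow(gt$pairs) > 0L) {
      if (ci == 1L) pair_id[gt$pairs$reference] <- seq_len(nrow(gt$pairs))
      if (ci == 2L) pair_id[gt$pairs$target] <- seq_len(nrow(gt$pairs))
    }
    rows[[ci]] <- data.frame(channel = chs[ci], index = seq_len(nrow(pos)),
                             x = pos[, "x"], y = pos[, "y"], z = pos[, "z"],
                             pair_id = pair_id)
  }
  df <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(channel = character(0), index = integer(0), x = numeric(0),
               y = numeric(0), z = numeric(0), pair_id = integer(0))
  }
  write.csv(df, path, row.names = FALSE)
  side <- list(channels = chs,
               phantom_volumes = as.list(gt$phantom_volumes),
               params = params_to_list(gt$params))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

# serialize a params object for the JSON sidecar / run manifests
params_to_list <- function(p) {
  if (is.null(p)) return(NULL)
  out <- lapply(unclass(p), function(v) {
    if (inherits(v, "voxel_size")) as.list(unclass(v)) else v
  })
  out
}

#' Read ground truth written by [write_ground_truth()]
#' @param path CSV path
#' @return a `ground_truth` (params restored as a plain list)
#' @export
read_ground_truth <- function(path) {
  df <- read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  chs <- side$channels
  pos <- lapply(chs, function(ch) {
    sub <- df[df$channel == ch, , drop = FALSE]
    sub <- sub[order(sub$index), , drop = FALSE]
    m <- as.matrix(sub[, c("x", "y", "z"), drop = FALSE])
    rownames(m) <- NULL
    m
  })
  names(pos) <- chs
  pairs <- NULL
  if (length(chs) >= 2L && any(!is.na(df$pair_id))) {
    r <- df[df$channel == chs[1L] & !is.na(df$pair_id), ]
    t <- df[df$channel == chs[2L] & !is.na(df$pair_id), ]
    pairs <- data.frame(reference = r$index[order(r$pair_id)],
                        target = t$index[order(t$pair_id)])
  }
  vols <- unlist(side$phantom_volumes)
  new_ground_truth(pos, pairs, if (length(vols)) vols else NULL,
                   side$params)
}
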