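# Cross-channel colocalization counting, Gaussian-KDE local density,
# overall puncta density, and normalization of group measurements to a
# reference group mean.

coords_or_set <- function(x) {
  if (inherits(x, "puncta_set")) puncta_coords(x) else puncta_coords(x)
}

#' Count colocalized reference puncta
#'
#' The number of reference (post-synaptic) puncta having at least one
#' target (pre-synaptic) punctum strictly within `radius_um` in physical
#' 3D distance. The count is asymmetric and existence-based: one target
#' punctum may satisfy several reference puncta. The strict `<` follows
#' the "< 200 nm" colocalization convention; each satisfied reference
#' punctum counts as one synapse.
#'
#' @param reference,target `puncta_set`s (must share the same image
#'   extent) or n x 3 coordinate matrices / data.frames with columns
#'   `x, y, z` in um.
#' @param radius_um colocalization radius in um (> 0); default 0.2.
#' @return integer count in `[0, n_reference]`.
#' @export
count_colocalized <- function(reference, target, radius_um = 0.2) {
  stopifnot(radius_um > 0)
  if (inherits(reference, "puncta_set") && inherits(target, "puncta_set")) {
    if (max(abs(reference$extent - target$extent)) > 1e-6) {
      stop("reference and target puncta sets have different image extents")
    }
  }
  ref <- coords_or_set(reference)
  tgt <- coords_or_set(target)
  if (nrow(ref) == 0L || nrow(tgt) == 0L) return(0L)
  r2 <- radius_um^2
  count <- 0L
  chunk <- 512L
  for (start in seq(1L, nrow(ref), by = chunk)) {
    ix <- start:min(start + chunk - 1L, nrow(ref))
    d2 <- outer(ref[ix, 1L], tgt[, 1L], "-")^2 +
      outer(ref[ix, 2L], tgt[, 2L], "-")^2 +
      outer(ref[ix, 3L], tgt[, 3L], "-")^2
    count <- count + sum(apply(d2 < r2, 1L, any))
  }
  as.integer(count)
}

#' Per-punctum local density by Gaussian kernel density estimation
#'
#' For punctum i, `density_i = sum_{j != i} K_h(||x_i - x_j||)` with the
#' 3D isotropic Gaussian kernel `K_h(d) = (2 pi h^2)^(-3/2)
#' exp(-d^2 / (2 h^2))`. The self-term is excluded (an isolated punctum
#' has local density 0) and no boundary correction is applied; units are
#' puncta per cubic micrometre.
#'
#' @param puncta a `puncta_set` or coordinate matrix (>= 1 punctum).
#' @param bandwidth_um kernel bandwidth h in um (> 0); default 0.4
#'   (twice the punctum diameter).
#' @return numeric vector of per-punctum densities (um^-3).
#' @export
local_density <- function(puncta, bandwidth_um = 0.4) {
  if (!is.numeric(bandwidth_um) || bandwidth_um <= 0) {
    stop("bandwidth_um must be positive")
  }
  pos <- coords_or_set(puncta)
  n <- nrow(pos)
  if (n == 0L) stop("local_density needs at least one punctum")
  if (n == 1L) return(0)
  d2 <- as.matrix(stats::dist(pos))^2
  k <- (2 * pi * bandwidth_um^2)^(-3 / 2) *
    exp(-d2 / (2 * bandwidth_um^2))
  diag(k) <- 0
  unname(rowSums(k))
}

#' Overall puncta density
#'
#' Puncta count divided by the analyzed physical volume.
#'
#' @param puncta a `puncta_set`, coordinate matrix, or a bare count.
#' @param analyzed_volume_um3 analyzed volume in um^3 (> 0); for
#'   edge-filtered detections use [analyzed_volume()] so the numerator's
#'   spatial domain matches the denominator.
#' @return density in puncta per um^3.
#' @export
overall_density <- function(puncta, analyzed_volume_um3) {
  if (!is.numeric(analyzed_volume_um3) || analyzed_volume_um3 <= 0) {
    stop("analyzed_volume_um3 must be positive")
  }
  n <- if (is.numeric(puncta) && length(puncta) == 1L) puncta else
    nrow(coords_or_set(puncta))
  n / analyzed_volume_um3
}

#' Analyzed volume of an image after edge exclusion
#'
#' Full physical stack extent minus the edge-exclusion margin on each
#' face, so that edge-excluded puncta do not deflate density estimates.
#'
#' @param extent named physical extent `c(x=, y=, z=)` um, or a
#'   `puncta_set` (whose extent and detection edge margin are used).
#' @param edge_margin_um margin excluded at every face (scalar or
#'   per-axis `c(x, y, z)`).
#' @return volume in um^3.
#' @export
analyzed_volume <- function(extent, edge_margin_um = NULL) {
  if (inherits(extent, "puncta_set")) {
    if (is.null(edge_margin_um)) {
      edge_margin_um <- extent$params$edge_margin_um
      if (is.null(edge_margin_um)) edge_margin_um <- 0
    }
    extent <- extent$extent
  }
  if (is.null(edge_margin_um)) edge_margin_um <- 0
  m <- rep_len(edge_margin_um, 3L)
  sides <- c(extent[["x"]] - 2 * m[1L], extent[["y"]] - 2 * m[2L],
             extent[["z"]] - 2 * m[3L])
  if (any(sides <= 0)) stop("edge margin consumes the whole extent")
  prod(sides)
}

#' Colocalization and density summary for one image
#'
#' Bundles the cross-channel colocalized count, per-channel overall
#' densities over the edge-corrected analyzed volume, and per-punctum
#' local KDE densities.
#'
#' @param reference,target `puncta_set`s from the same image.
#' @param radius_um colocalization radius (um).
#' @param bandwidth_um KDE bandwidth (um).
#' @return object of class `coloc_density_result`.
#' @export
coloc_density <- function(reference, target, radius_um = 0.2,
                          bandwidth_um = 0.4) {
  stopifnot(inherits(reference, "puncta_set"),
            inherits(target, "puncta_set"))
  vol <- analyzed_volume(reference)
  n_ref <- n_puncta(reference)
  n_tgt <- n_puncta(target)
  res <- list(
    n_reference = n_ref, n_target = n_tgt,
    n_colocalized = count_colocalized(reference, target, radius_um),
    coloc_radius = radius_um,
    overall_density = c(reference = overall_density(n_ref, vol),
                        target = overall_density(n_tgt, vol)),
    analyzed_volume = vol,
    local_densities = list(
      reference = if (n_ref > 0L) local_density(reference, bandwidth_um)
        else numeric(0),
      target = if (n_tgt > 0L) local_density(target, bandwidth_um)
        else numeric(0)),
    kde_bandwidth = bandwidth_um,
    channels = c(reference = reference$channel, target = target$channel))
  class(res) <- "coloc_density_result"
  res
}

#' @export
print.coloc_density_result <- function(x, ...) {
  cat(sprintf(paste0(
    "coloc_density_result: %d/%d reference puncta colocalized ",
    "(radius %.3g um)\n"), x$n_colocalized, x$n_reference, x$coloc_radius))
  cat(sprintf("  densities: reference %.4g, target %.4g puncta/um^3 over %.4g um^3\n",
              x$overall_density[["reference"]],
              x$overall_density[["target"]], x$analyzed_volume))
  invisible(x)
}

#' Normalize group measurements to a reference group mean
#'
#' Divides each value by the mean of the reference group (e.g. 4-month
#' wild-type) for the same measurement — and, when a `region` column is
#' present, the same region, since regions are normalized separately.
#' The reference group's normalized mean is exactly 1.
#'
#' @param table data.frame in long format with a `value` column, a
#'   `measurement` column, optionally `region`, and the grouping columns
#'   named in `reference`.
#' @param reference named character vector identifying the reference
#'   group, e.g. `c(age_group = "4mo", genotype = "WT")`.
#' @return the table with a `normalized_value` column added.
#' @export
normalize_to_reference <- function(table,
                                   reference = c(age_group = "4mo",
                                                 genotype = "WT")) {
  stopifnot(is.data.frame(table), "value" %in% names(table),
            "measurement" %in% names(table),
            all(names(reference) %in% names(table)))
  by_cols <- intersect(c("measurement", "region"), names(table))
  key <- interaction(table[by_cols], drop = TRUE)
  table$normalized_value <- NA_real_
  is_ref <- rep(TRUE, nrow(table))
  for (col in names(reference)) {
    is_ref <- is_ref & table[[col]] == reference[[col]]
  }
  for (lev in levels(key)) {
    rows <- key == lev
    ref_vals <- table$value[rows & is_ref]
    if (length(ref_vals) == 0L) {
      stop(sprintf("no reference-group rows for group '%s'", lev))
    }
    ref_mean <- mean(ref_vals)
    if (ref_mean == 0) {
      stop(sprintf("reference group mean is zero for group '%s'", lev))
    }
    table$normalized_value[rows] <- table$value[rows] / ref_mean
  }
  table
}
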