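vox_tissue <- voxel_size(0.1, 0.1, 0.125)

# single noiseless blob rendered by the generator, with its true centre
one_blob <- function(seed = 21, fwhm = 0.2) {
  fp <- puncta_field_params(shape = c(16, 64, 64), voxel = vox_tissue,
                            n_reference = 1, n_target = 0,
                            coloc_fraction = 0, punctum_fwhm = fwhm,
                            amplitude_cv = 0, shot_noise = FALSE,
                            read_noise_sd = 0, seed = seed)
  f <- generate_puncta_field(fp)
  list(ch = get_channel(f$image, 1), center = f$truth$positions[[1]][1, ])
}

test_that("LoG response vanishes on flat images and peaks at a matched blob", {
  flat <- array(7, c(6, 20, 20))
  resp <- log_response(flat, vox_tissue, 0.2)
  expect_lt(max(abs(resp)), 1e-9)

  b <- one_blob()
  resp <- log_response(b$ch, vox_tissue, 0.2)
  pk <- which(resp == max(resp), arr.ind = TRUE)[1, ]
  pk_um <- c((pk[3] - 0.5) * 0.1, (pk[2] - 0.5) * 0.1,
             (pk[1] - 0.5) * 0.125)
  # global maximum within half a voxel of the blob centre, per axis
  expect_true(all(abs(pk_um - b$center) <=
                    c(0.05, 0.05, 0.0625) + 1e-9))
})

test_that("LoG response is scale selective", {
  b <- one_blob()
  iz <- floor(b$center["z"] / 0.125) + 1
  iy <- floor(b$center["y"] / 0.1) + 1
  ix <- floor(b$center["x"] / 0.1) + 1
  matched <- log_response(b$ch, vox_tissue, 0.2)[iz, iy, ix]
  off <- log_response(b$ch, vox_tissue, 0.4)[iz, iy, ix]
  expect_gt(matched, off)
})

test_that("LoG rejects bad diameters and warns on undersampled scales", {
  flat <- array(1, c(4, 8, 8))
  expect_error(log_response(flat, vox_tissue, -1), "positive")
  expect_warning(log_response(flat, vox_tissue, 0.15), "undersampled")
})

test_that("local maxima equal the brute-force neighbourhood scan", {
  withr::with_seed(31, resp <- array(rnorm(5 * 7 * 6), c(5, 7, 6)))
  cands <- find_local_maxima(resp, vox_tissue)
  oracle <- oracle_maxima_mask(resp)
  # strict random field: no plateaus, so candidates are exactly the
  # oracle voxels
  ai <- which(oracle, arr.ind = TRUE)
  expect_equal(nrow(cands), nrow(ai))
  got <- cands[order(cands$x, cands$y, cands$z), ]
  want <- data.frame(x = (ai[, 3] - 0.5) * 0.1, y = (ai[, 2] - 0.5) * 0.1,
                     z = (ai[, 1] - 0.5) * 0.125)
  want <- want[order(want$x, want$y, want$z), ]
  expect_equal(got$x, want$x, tolerance = 1e-12)
  expect_equal(got$y, want$y, tolerance = 1e-12)
  expect_equal(got$z, want$z, tolerance = 1e-12)
})

test_that("a strictly concave peak gives one candidate; a constant field one plateau", {
  z <- seq(-1, 1, length.out = 9)
  field <- -outer(outer(z^2, z^2, "+"), z^2, "+")
  dim(field) <- c(9, 9, 9)
  cands <- find_local_maxima(field, voxel_size(0.1, 0.1, 0.1))
  expect_equal(nrow(cands), 1L)

  const <- array(4, c(4, 5, 6))
  cands <- find_local_maxima(const, voxel_size(0.1, 0.1, 0.1))
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$n_voxels, 4L * 5L * 6L)
})

test_that("merging follows single-linkage at the merge radius", {
  two_close <- data.frame(x = c(1, 1.10), y = c(1, 1), z = c(1, 1),
                          response = c(2, 1), raw_intensity = c(5, 4),
                          n_voxels = 1L)
  m <- merge_candidates(two_close, 0.2)
  expect_equal(nrow(m), 1L)
  expect_equal(m$n_merged, 2L)
  # response-weighted centroid: weights 2/3 and 1/3
  expect_equal(m$x, 1 * 2 / 3 + 1.10 / 3, tolerance = 1e-12)
  expect_equal(m$response, 2)

  two_far <- transform(two_close, x = c(1, 1.25))
  expect_equal(nrow(merge_candidates(two_far, 0.2)), 2L)

  chain <- data.frame(x = c(1, 1.15, 1.30), y = 1, z = 1,
                      response = 1, raw_intensity = 1, n_voxels = 1L)
  m <- merge_candidates(chain, 0.2)
  expect_equal(nrow(m), 1L)
  expect_equal(m$n_merged, 3L)
})

test_that("merging equals an independent union-find oracle on random sets", {
  for (s in 1:10) {
    withr::with_seed(400 + s, {
      n <- sample(5:60, 1)
      coords <- cbind(runif(n, 0, 3), runif(n, 0, 3), runif(n, 0, 1))
    })
    cand <- data.frame(x = coords[, 1], y = coords[, 2], z = coords[, 3],
                       response = 1, raw_intensity = 1, n_voxels = 1L)
    m <- merge_candidates(cand, 0.25)
    oracle_comp <- oracle_single_linkage(coords, 0.25)
    expect_equal(nrow(m), length(unique(oracle_comp)))
    # same partition: each oracle component's centroid appears once
    for (g in unique(oracle_comp)) {
      ctr <- colMeans(coords[oracle_comp == g, , drop = FALSE])
      d <- sqrt((m$x - ctr[1])^2 + (m$y - ctr[2])^2 + (m$z - ctr[3])^2)
      expect_lt(min(d), 1e-9)
    }
  }
})

test_that("merging is invariant to candidate order", {
  withr::with_seed(41, {
    cand <- data.frame(x = runif(40, 0, 2), y = runif(40, 0, 2),
                       z = runif(40, 0, 1),
                       response = runif(40, 0.5, 2),
                       raw_intensity = runif(40), n_voxels = 1L)
  })
  m1 <- merge_candidates(cand, 0.3)
  m2 <- merge_candidates(cand[rev(seq_len(40)), ], 0.3)
  expect_equal(m1$x, m2$x, tolerance = 1e-9)
  expect_equal(m1$y, m2$y, tolerance = 1e-9)
  expect_equal(m1$z, m2$z, tolerance = 1e-9)
})

test_that("Otsu threshold separates well-separated classes and matches the exhaustive scan", {
  sample1 <- c(rep(0, 10), rep(100, 10))
  thr <- otsu_threshold(sample1)
  expect_gt(thr, 0)
  expect_lt(thr, 100)
  expect_equal(thr, oracle_otsu(sample1))

  withr::with_seed(51, {
    sample2 <- c(rnorm(400, 20, 5), rnorm(400, 200, 5))
  })
  thr2 <- otsu_threshold(sample2)
  expect_true(all(sample2[sample2 < thr2] < 100))
  expect_true(all(sample2[sample2 > thr2] > 100))
  expect_equal(thr2, oracle_otsu(sample2))

  expect_error(otsu_threshold(rep(3, 10)), "degenerate")
})

test_that("edge and intensity filters remove exactly the flagged puncta", {
  extent <- c(x = 2, y = 2, z = 1)
  p <- data.frame(x = c(0.05, 0.5, 1.0, 1.5), y = c(0.5, 0.5, 0.5, 0.5),
                  z = c(0.5, 0.5, 0.5, 0.5),
                  response = 1, raw_intensity = c(10, 2, 10, 10),
                  n_merged = 1L)
  out <- filter_candidates(p, extent, 0.1, gate_threshold = NULL)
  expect_equal(out$x, c(0.5, 1.0, 1.5)) # edge punctum removed
  out2 <- filter_candidates(p, extent, 0.1, gate_threshold = 5)
  expect_equal(out2$x, c(1.0, 1.5)) # and the dim one
  # all interior and bright: identity
  out3 <- filter_candidates(p[3:4, ], extent, 0.1, gate_threshold = 5)
  expect_equal(nrow(out3), 2L)
})

test_that("blank images yield an empty puncta set", {
  img <- image_stack(array(5, c(8, 32, 32, 1)), vox_tissue, "Homer1")
  ps <- detect_puncta(img, "Homer1")
  expect_equal(n_puncta(ps), 0L)
})

test_that("well-separated noiseless blobs are each recovered within half a voxel", {
  fp <- puncta_field_params(shape = c(16, 96, 96), voxel = vox_tissue,
                            n_reference = 5, n_target = 0,
                            coloc_fraction = 0, amplitude_cv = 0,
                            shot_noise = FALSE, read_noise_sd = 0,
                            min_separation = 1.0, seed = 61)
  f <- generate_puncta_field(fp)
  ps <- detect_puncta(f$image, 1)
  expect_equal(n_puncta(ps), 5L)
  m <- match_points(f$truth$positions[[1]], ps, 0.2)
  expect_equal(m$n_matched, 5L)
  expect_true(all(m$errors < 0.5 * sqrt(0.1^2 + 0.1^2 + 0.125^2)))
})

test_that("detection is equivariant to intensity scaling", {
  fp <- tiny_field_params(seed = 71)
  f <- generate_puncta_field(fp)
  ps1 <- detect_puncta(f$image, 1)
  scaled <- f$image
  scaled$intensities <- scaled$intensities * 3.7
  ps2 <- detect_puncta(scaled, 1)
  expect_equal(n_puncta(ps1), n_puncta(ps2))
  expect_equal(ps1$puncta$x, ps2$puncta$x, tolerance = 1e-9)
  expect_equal(ps1$puncta$z, ps2$puncta$z, tolerance = 1e-9)
})

test_that("no two detected puncta lie within the merge radius", {
  for (s in 81:83) {
    fp <- tiny_field_params(seed = s)
    f <- generate_puncta_field(fp)
    ps <- detect_puncta(f$image, 1)
    if (n_puncta(ps) >= 2) {
      expect_gte(min(dist(puncta_coords(ps))),
                 ps$params$merge_radius_um)
    }
  }
})

test_that("recovery F1 degrades monotonically with read noise", {
  f1_at <- function(noise_sd) {
    f1 <- numeric(0)
    for (s in 1:5) {
      fp <- puncta_field_params(shape = c(12, 128, 128),
                                n_reference = 60, n_target = 0,
                                coloc_fraction = 0,
                                read_noise_sd = noise_sd,
                                seed = 900 + s)
      f <- generate_puncta_field(fp)
      ps <- detect_puncta(f$image, 1)
      f1 <- c(f1, match_points(f$truth$positions[[1]], ps, 0.2)$f1)
    }
    mean(f1)
  }
  f1s <- vapply(c(0, 15, 40), f1_at, numeric(1))
  expect_gte(f1s[1] + 0.02, f1s[2])
  expect_gte(f1s[2] + 0.02, f1s[3])
})

test_that("DoG detection finds projected culture puncta", {
  # culture geometry: 0.4 um z-steps, max projection, 0.72 um blobs
  fp <- puncta_field_params(shape = c(6, 128, 128),
                            voxel = voxel_size(0.1, 0.1, 0.4),
                            n_reference = 12, n_target = 0,
                            coloc_fraction = 0, punctum_fwhm = 0.72,
                            min_separation = 1.6, edge_margin = 1.0,
                            amplitude_cv = 0, shot_noise = TRUE,
                            read_noise_sd = 0, seed = 91)
  f <- generate_puncta_field(fp)
  dp <- detection_params(punctum_diameter_um = 0.72, mode = "dog2d",
                         edge_margin_um = 0.36)
  ps <- detect_puncta(f$image, 1, dp)
  truth_xy <- f$truth$positions[[1]]
  truth_xy[, "z"] <- ps$puncta$z[1] # compare in the projected plane
  m <- match_points(truth_xy, ps, 0.36)
  expect_gte(m$recall, 0.9)
  expect_gte(m$precision, 0.8)
})
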