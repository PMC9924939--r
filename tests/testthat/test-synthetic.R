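test_that("empty field is background plus nothing, with empty ground truth", {
  fp <- puncta_field_params(shape = c(6, 32, 32), n_reference = 0,
                            n_target = 0, coloc_fraction = 0,
                            shot_noise = FALSE, read_noise_sd = 0,
                            seed = 1)
  f <- generate_puncta_field(fp)
  expect_equal(as.vector(f$image$intensities),
               rep(fp$background_level, 2 * 6 * 32 * 32))
  expect_equal(nrow(f$truth$positions[[1]]), 0L)
  expect_equal(nrow(f$truth$positions[[2]]), 0L)
  expect_equal(nrow(f$truth$pairs), 0L)
})

test_that("pair count is round-half-up of n_reference * coloc_fraction", {
  fp <- puncta_field_params(shape = c(12, 128, 128), n_reference = 200,
                            n_target = 200, coloc_fraction = 0.4,
                            seed = 2)
  f <- generate_puncta_field(fp)
  expect_equal(nrow(f$truth$pairs), 80L)
  expect_warning(
    puncta_field_params(n_reference = 150, coloc_fraction = 0.333),
    "not an integer")
  expect_equal(round_half_up(c(2.5, 3.5, 2.4, -0.2)), c(3, 4, 2, 0))
})

test_that("zero coloc_fraction with wide separation yields zero true colocalization", {
  fp <- tiny_field_params(coloc_fraction = 0, min_separation = 0.3,
                          seed = 3)
  f <- generate_puncta_field(fp)
  expect_equal(
    brute_force_coloc(f$truth$positions[[1]], f$truth$positions[[2]], 0.2),
    0L)
})

test_that("identical params and seed give bit-identical output", {
  fp <- tiny_field_params(seed = 11)
  f1 <- generate_puncta_field(fp)
  f2 <- generate_puncta_field(fp)
  expect_identical(f1$image$intensities, f2$image$intensities)
  expect_identical(f1$truth$positions, f2$truth$positions)
  expect_identical(f1$truth$pairs, f2$truth$pairs)
})

test_that("pairing offsets and same-channel separations respect the parameters", {
  for (s in 1:100) {
    fp <- puncta_field_params(shape = c(8, 64, 64), n_reference = 15,
                              n_target = 15, coloc_fraction = 0.4,
                              pair_offset_max = 0.15,
                              min_separation = 0.3, shot_noise = FALSE,
                              seed = 100 + s)
    f <- generate_puncta_field(fp)
    ref <- f$truth$positions[[1]]
    tgt <- f$truth$positions[[2]]
    for (k in seq_len(nrow(f$truth$pairs))) {
      d <- sqrt(sum((ref[f$truth$pairs$reference[k], ] -
                       tgt[f$truth$pairs$target[k], ])^2))
      expect_lte(d, fp$pair_offset_max)
    }
    for (pos in list(ref, tgt)) {
      if (nrow(pos) >= 2) {
        expect_gte(min(dist(pos)), fp$min_separation)
      }
    }
  }
})

test_that("noiseless photometry at punctum centres matches background + amplitude", {
  # FWHM 0.2 um at 0.02 um isotropic voxels (10 voxels per FWHM): the
  # voxel containing each centre sits at most half a voxel diagonal
  # (0.017 um) from it, so midpoint rendering keeps the peak within 5%
  # of background + amplitude
  fp <- puncta_field_params(shape = c(40, 100, 100),
                            voxel = voxel_size(0.02, 0.02, 0.02),
                            n_reference = 4, n_target = 0,
                            coloc_fraction = 0, amplitude_cv = 0,
                            shot_noise = FALSE, read_noise_sd = 0,
                            seed = 5)
  f <- generate_puncta_field(fp)
  ch <- get_channel(f$image, 1)
  pos <- f$truth$positions[[1]]
  for (i in seq_len(nrow(pos))) {
    iz <- floor(pos[i, "z"] / 0.02) + 1
    iy <- floor(pos[i, "y"] / 0.02) + 1
    ix <- floor(pos[i, "x"] / 0.02) + 1
    expect_lt(abs(ch[iz, iy, ix] -
                    (fp$background_level + fp$amplitude_mean)) /
                fp$amplitude_mean, 0.05)
  }
})

test_that("placement failure names the separation constraint", {
  fp <- puncta_field_params(shape = c(4, 16, 16), n_reference = 500,
                            n_target = 0, coloc_fraction = 0,
                            min_separation = 0.5, seed = 6)
  expect_error(generate_puncta_field(fp), "min_separation")
})

test_that("engulfment phantom records analytic volumes and respects degenerate cargo", {
  ep <- engulfment_phantom_params(seed = 7)
  ph <- generate_engulfment_phantom(ep)
  vols <- ph$truth$phantom_volumes
  expect_equal(unname(vols["cell"]), 4 / 3 * pi * 27, tolerance = 1e-12)
  expect_equal(unname(vols["lysosome"]), 4 / 3 * pi * 1.5^3,
               tolerance = 1e-12)
  expect_equal(unname(vols["cargo"]), 4 / 3 * pi * 0.125,
               tolerance = 1e-12)

  # voxel-count volume of the painted cell at 0.1 um voxels: within 5%
  ep0 <- engulfment_phantom_params(read_noise_sd = 0)
  ph0 <- generate_engulfment_phantom(ep0)
  cell_vox <- sum(get_channel(ph0$image, "Iba1") > ep0$background_level)
  expect_lt(abs(cell_vox * 0.001 - vols[["cell"]]) / vols[["cell"]], 0.05)

  ep_blank <- engulfment_phantom_params(cargo = list(center = NULL,
                                                     radius = 0),
                                        read_noise_sd = 0)
  ph_blank <- generate_engulfment_phantom(ep_blank)
  expect_equal(unname(ph_blank$truth$phantom_volumes["cargo"]), 0)
  expect_true(all(get_channel(ph_blank$image, "Vglut1") ==
                    ep_blank$background_level))
})

test_that("invalid engulfment geometry errors", {
  expect_error(generate_engulfment_phantom(
    engulfment_phantom_params(lysosome = list(center = NULL, radius = 4))),
    "not nested")
  expect_error(generate_engulfment_phantom(
    engulfment_phantom_params(cell = list(center = c(1, 1, 1), radius = 3),
                              lysosome = list(center = c(1, 1, 1),
                                              radius = 1.5),
                              cargo = list(center = c(1, 1, 1),
                                           radius = 0.5))),
    "escapes")
})

test_that("ground truth round-trips through CSV + sidecar", {
  fp <- puncta_field_params(shape = c(12, 128, 128), n_reference = 200,
                            n_target = 200, coloc_fraction = 0.4,
                            seed = 8)
  f <- generate_puncta_field(fp)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(f$truth, path)
  df <- read.csv(path)
  expect_equal(sum(!is.na(df$pair_id)), 160L)
  expect_equal(length(unique(df$pair_id[!is.na(df$pair_id)])), 80L)
  gt2 <- read_ground_truth(path)
  expect_equal(gt2$positions[[1]], f$truth$positions[[1]],
               tolerance = 1e-12)
  expect_equal(gt2$positions[[2]], f$truth$positions[[2]],
               tolerance = 1e-12)
  expect_equal(gt2$pairs, f$truth$pairs)
})

test_that("empty ground truth writes a header-only CSV", {
  fp <- puncta_field_params(shape = c(4, 16, 16), n_reference = 0,
                            n_target = 0, coloc_fraction = 0, seed = 9)
  f <- generate_puncta_field(fp)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(f$truth, path)
  expect_equal(nrow(read.csv(path)), 0L)
})
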