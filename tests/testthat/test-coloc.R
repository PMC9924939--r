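rand_points <- function(n, box = c(20, 20, 2), seed = 1) {
  withr::with_seed(seed, {
    cbind(x = runif(n, 0, box[1]), y = runif(n, 0, box[2]),
          z = runif(n, 0, box[3]))
  })
}

test_that("colocalization count handles empty and identical sets", {
  a <- rand_points(50, seed = 2)
  none <- a[0, , drop = FALSE]
  expect_equal(count_colocalized(none, a, 0.2), 0L)
  expect_equal(count_colocalized(a, none, 0.2), 0L)
  expect_equal(count_colocalized(a, a, 0.05), 50L) # zero self-distance
})

test_that("colocalization count equals the brute-force oracle on random sets", {
  for (s in 1:8) {
    withr::with_seed(s, {
      n1 <- sample(50:300, 1)
      n2 <- sample(50:300, 1)
    })
    a <- rand_points(n1, seed = 1000 + s)
    b <- rand_points(n2, seed = 2000 + s)
    expect_equal(count_colocalized(a, b, 0.2),
                 brute_force_coloc(a, b, 0.2))
  }
})

test_that("colocalization uses a strict inequality at the radius", {
  a <- cbind(x = 0, y = 0, z = 0)
  b <- cbind(x = 0.2, y = 0, z = 0)
  expect_equal(count_colocalized(a, b, 0.2), 0L)
  expect_equal(count_colocalized(a, b, 0.2000001), 1L)
})

test_that("colocalization count is monotone in the radius and bounded by |reference|", {
  a <- rand_points(120, seed = 3)
  b <- rand_points(150, seed = 4)
  radii <- c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6)
  counts <- vapply(radii, function(r) count_colocalized(a, b, r),
                   integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_true(all(counts <= nrow(a)))
  expect_equal(count_colocalized(a, rbind(b, a), 0.1), nrow(a))
})

test_that("mismatched image extents are rejected", {
  fp <- tiny_field_params(seed = 5)
  f <- generate_puncta_field(fp)
  ps1 <- detect_puncta(f$image, 1)
  ps2 <- detect_puncta(f$image, 2)
  ps2$extent["x"] <- ps2$extent["x"] * 2
  expect_error(count_colocalized(ps1, ps2, 0.2), "extent")
})

test_that("local KDE density matches closed forms and the naive double loop", {
  # an isolated punctum has zero local density (self-term excluded)
  expect_equal(local_density(cbind(x = 1, y = 1, z = 1), 0.4), 0)
  # two coincident puncta: each sees the kernel's value at distance 0
  two <- cbind(x = c(1, 1), y = c(1, 1), z = c(1, 1))
  h <- 0.3
  expect_equal(local_density(two, h),
               rep((2 * pi * h^2)^(-3 / 2), 2), tolerance = 1e-12)

  for (s in 1:5) {
    pts <- rand_points(50, box = c(5, 5, 2), seed = 300 + s)
    got <- local_density(pts, 0.4)
    want <- numeric(50)
    for (i in 1:50) {
      acc <- 0
      for (j in 1:50) {
        if (i == j) next
        d2 <- sum((pts[i, ] - pts[j, ])^2)
        acc <- acc + (2 * pi * 0.4^2)^(-3 / 2) * exp(-d2 / (2 * 0.4^2))
      }
      want[i] <- acc
    }
    expect_equal(got, want, tolerance = 1e-10)
  }
  expect_error(local_density(two, 0), "positive")
})

test_that("overall density is count over volume", {
  pts <- rand_points(100, seed = 6)
  expect_equal(overall_density(pts, 200), 0.5)
  expect_equal(overall_density(pts[0, , drop = FALSE], 200), 0)
  expect_error(overall_density(pts, 0), "positive")
})

test_that("analyzed volume removes the edge margin on every face", {
  expect_equal(analyzed_volume(c(x = 10, y = 10, z = 2), 0.1),
               9.8 * 9.8 * 1.8)
  expect_error(analyzed_volume(c(x = 1, y = 1, z = 0.1), 0.1),
               "margin")
})

test_that("density is stable across voxel sizes for the same physical field", {
  base <- list(n_reference = 40, n_target = 0, coloc_fraction = 0,
               amplitude_cv = 0, shot_noise = FALSE, read_noise_sd = 0,
               min_separation = 0.4, seed = 777)
  f1 <- generate_puncta_field(do.call(puncta_field_params, c(
    list(shape = c(16, 128, 128), voxel = voxel_size(0.1, 0.1, 0.125)),
    base)))
  f2 <- generate_puncta_field(do.call(puncta_field_params, c(
    list(shape = c(25, 160, 160), voxel = voxel_size(0.08, 0.08, 0.08)),
    base)))
  d <- vapply(list(f1, f2), function(f) {
    ps <- detect_puncta(f$image, 1)
    overall_density(n_puncta(ps), analyzed_volume(ps))
  }, numeric(1))
  expect_lt(abs(d[1] - d[2]) / d[1], 0.1)
})

test_that("coloc_density bundles counts, densities and local KDE output", {
  fp <- tiny_field_params(seed = 7)
  f <- generate_puncta_field(fp)
  ps1 <- detect_puncta(f$image, 1)
  ps2 <- detect_puncta(f$image, 2)
  cd <- coloc_density(ps1, ps2)
  expect_lte(cd$n_colocalized, cd$n_reference)
  expect_equal(cd$overall_density[["reference"]] * cd$analyzed_volume,
               cd$n_reference, tolerance = 1e-9)
  expect_equal(length(cd$local_densities$reference), cd$n_reference)
  expect_true(all(cd$local_densities$reference >= 0))
})

test_that("normalization to the reference group is per measurement and region", {
  tab <- expand.grid(animal = 1:4, age_group = c("4mo", "17mo"),
                     genotype = c("WT", "KO"),
                     region = c("cortex", "CA1"),
                     measurement = c("synaptic_density",
                                     "target_density"),
                     stringsAsFactors = FALSE)
  withr::with_seed(8, tab$value <- runif(nrow(tab), 1, 5))
  out <- normalize_to_reference(tab, c(age_group = "4mo",
                                       genotype = "WT"))
  for (rg in c("cortex", "CA1")) {
    for (mm in unique(tab$measurement)) {
      sel <- out$region == rg & out$measurement == mm
      ref <- sel & out$age_group == "4mo" & out$genotype == "WT"
      # the reference group's normalized mean is exactly 1
      expect_equal(mean(out$normalized_value[ref]), 1, tolerance = 1e-12)
      ref_mean <- mean(out$value[ref])
      expect_equal(out$normalized_value[sel],
                   out$value[sel] / ref_mean, tolerance = 1e-12)
    }
  }
  # a value equal to the reference mean normalizes to exactly 1
  tab2 <- data.frame(age_group = c("4mo", "4mo", "17mo"),
                     genotype = "WT", measurement = "m",
                     value = c(2, 4, 3))
  out2 <- normalize_to_reference(tab2, c(age_group = "4mo",
                                         genotype = "WT"))
  expect_equal(out2$normalized_value, c(2 / 3, 4 / 3, 1))
  expect_error(normalize_to_reference(
    data.frame(age_group = "17mo", genotype = "KO", measurement = "m",
               value = 1),
    c(age_group = "4mo", genotype = "WT")), "reference")
})

test_that("chance colocalization follows the Poisson closed form", {
  # independent homogeneous channels at intensity lambda: the chance
  # that a reference punctum has >= 1 target within r is
  # 1 - exp(-lambda * (4/3) pi r^3)
  lambda <- 0.3
  box <- c(20, 20, 2)
  r <- 0.2
  expected <- 1 - exp(-lambda * 4 / 3 * pi * r^3)
  fracs <- numeric(60)
  withr::with_seed(99, {
    for (i in seq_along(fracs)) {
      n1 <- rpois(1, lambda * prod(box))
      n2 <- rpois(1, lambda * prod(box))
      a <- cbind(runif(n1, 0, box[1]), runif(n1, 0, box[2]),
                 runif(n1, 0, box[3]))
      b <- cbind(runif(n2, 0, box[1]), runif(n2, 0, box[2]),
                 runif(n2, 0, box[3]))
      colnames(a) <- colnames(b) <- c("x", "y", "z")
      fracs[i] <- if (n1 > 0) count_colocalized(a, b, r) / n1 else NA
    }
  })
  fracs <- fracs[!is.na(fracs)]
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - expected), 3 * se)
})
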