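test_that("case generation is deterministic and honors probability switches", {
  p <- small_params()
  a <- generate_case(p, 42)
  b <- generate_case(p, 42)
  expect_identical(a$image$voxels, b$image$voxels)
  expect_identical(a$labels$labels, b$labels$labels)

  p0 <- small_params(scar_probability = 0)
  for (s in 1:3) {
    ca <- generate_case(p0, s)
    expect_false(any(ca$labels$labels %in% c(3L, 4L)))
  }
  p1 <- small_params(scar_probability = 1, mvo_probability_given_scar = 0)
  for (s in 1:3) {
    ca <- generate_case(p1, s)
    expect_true(any(ca$labels$labels == 3L))
    expect_false(any(ca$labels$labels == 4L))
  }
})

test_that("invalid parameters are rejected naming the violated field", {
  expect_error(small_params(scar_probability = 1.2), "scar_probability")
  expect_error(small_params(endo_radius_mm = c(16, 20)), "epi_radius_mm")
  expect_error(phantom_params(grid_shape = c(0, 64, 64)), "grid_shape")
  expect_error(small_params(intensity_means = c(background = 50, blood = 320,
                                                myocardium = 200, scar = 190,
                                                mvo = 170)),
               "intensity_means")
  expect_error(small_params(intensity_means = c(background = 50, blood = 320,
                                                myocardium = 200, scar = 450,
                                                mvo = 250)),
               "intensity_means")
  expect_error(small_params(noise_sd = -1), "noise_sd")
})

test_that("generated geometry satisfies the label-nesting invariants", {
  p <- small_params(scar_probability = 1, mvo_probability_given_scar = 1,
                    seed = 3)
  for (s in 1:5) {
    ca <- generate_case(p, s)
    labs <- ca$labels$labels
    meta <- ca$meta
    d <- dim(labs)
    # recompute the annulus geometry from the drawn parameters (independent
    # of the generator's own rasterization loop ordering)
    rows <- matrix(rep(seq_len(d[2]), d[3]), d[2], d[3])
    cols <- matrix(rep(seq_len(d[3]), each = d[2]), d[2], d[3])
    dist_mm <- sqrt((rows - meta$center_rc[1])^2 +
                      (cols - meta$center_rc[2])^2) * ca$labels$spacing_mm[2]
    for (sl in seq_len(d[1])) {
      sc <- 1 - (1 - p$apex_taper) * (sl - 1) / (d[1] - 1)
      ring <- dist_mm > meta$endo_radius_mm * sc &
        dist_mm <= meta$epi_radius_mm * sc
      # scar and MVO voxels live inside the myocardial ring
      expect_true(all(ring[labs[sl, , ] %in% c(3L, 4L)]))
      # ring voxels carry a myocardial-tissue code
      expect_true(all(labs[sl, , ][ring] %in% c(2L, 3L, 4L)))
    }
    # MVO slices nest inside scar slices
    expect_true(all(meta$mvo_slices %in% meta$scar_slices))
    # MVO is angularly and radially inside the scar wedge: every MVO voxel
    # on a slice coexists with scar on that slice
    for (sl in seq_len(d[1]))
      if (any(labs[sl, , ] == 4L)) expect_true(any(labs[sl, , ] == 3L))
  }
})

test_that("scar is hyperintense relative to the remote ROI", {
  p <- small_params(scar_probability = 1)
  for (s in 1:3) {
    ca <- generate_case(p, s)
    roi <- remote_roi(ca)
    scar_mean <- mean(ca$image$voxels[ca$labels$labels == 3L])
    remote_mean <- mean(ca$image$voxels[roi])
    expect_gt(scar_mean, remote_mean + 3 * 25)
  }
})

test_that("remote ROI is myocardial, scar-free and diametrally opposite", {
  p <- small_params(scar_probability = 1, seed = 9)
  for (s in 1:5) {
    ca <- generate_case(p, s)
    roi <- remote_roi(ca)
    labs <- ca$labels$labels
    expect_true(any(roi))
    expect_true(all(labs[roi] == 2L))
    expect_false(any(roi & labs == 3L))
    expect_false(any(roi & labs == 4L))
    # centroid angle within +/- 45 degrees of the scar-opposite direction
    idx <- which(roi, arr.ind = TRUE)
    ctr <- ca$meta$center_rc
    ang <- (atan2(idx[, 2] - ctr[1], idx[, 3] - ctr[2]) * 180 / pi) %% 360
    # circular mean
    roi_ang <- (atan2(mean(sin(ang * pi / 180)),
                      mean(cos(ang * pi / 180))) * 180 / pi) %% 360
    opp <- (ca$meta$scar_theta0_deg + ca$meta$scar_extent_deg / 2 + 180) %% 360
    dd <- min(abs(roi_ang - opp), 360 - abs(roi_ang - opp))
    expect_lt(dd, 45)
  }
  # no-scar case: ROI still nonempty and myocardial
  ca0 <- generate_case(small_params(scar_probability = 0), 1)
  roi0 <- remote_roi(ca0)
  expect_true(any(roi0))
  expect_true(all(ca0$labels$labels[roi0] == 2L))
  # degenerate case without myocardium
  fake <- generate_case(small_params(), 1)
  fake$labels$labels[] <- 0L
  expect_error(remote_roi(fake), "no myocardium")
})

test_that("datasets use distinct seeds and match the target MVO prevalence", {
  expect_error(generate_dataset(small_params(), 0), "n_cases")
  one <- generate_dataset(small_params(), 1)
  expect_length(one, 1)
  expect_s3_class(one[[1]], "phantom_case")

  a <- generate_dataset(small_params(seed = 1), 3)
  b <- generate_dataset(small_params(seed = 2), 3)
  expect_false(identical(a[[1]]$image$voxels, b[[1]]$image$voxels))
  seeds <- vapply(a, function(x) x$meta$case_seed, integer(1))
  expect_length(unique(seeds), 3)

  # MVO-positive fraction stays in the binomial 95% band around
  # scar_probability * mvo_probability_given_scar = 0.15
  p <- small_params(seed = 11, scar_probability = 1,
                    mvo_probability_given_scar = 0.15)
  cases <- generate_dataset(p, 200)
  n_mvo <- sum(vapply(cases, function(x) x$meta$has_mvo, logical(1)))
  band <- stats::qbinom(c(0.025, 0.975), 200, 0.15)
  expect_gte(n_mvo, band[1])
  expect_lte(n_mvo, band[2])
})

test_that("a dataset round-trips through NIfTI files and a manifest", {
  dir <- withr::local_tempdir()
  cases <- generate_dataset(small_params(), 2)
  manifest <- write_dataset(cases, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(manifest), 2)
  img <- read_volume(manifest$image[1])
  lab <- read_volume(manifest$labels[1], as = "labels")
  expect_identical(img$voxels, cases[[1]]$image$voxels)
  expect_identical(lab$labels, cases[[1]]$labels$labels)
})
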