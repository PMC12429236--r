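test_that("2D segmenter outputs normalized per-class probabilities", {
  rep <- pipeline_fixture()
  ca <- crop_case(fixture_test_cases()[[1]])
  pr <- predict_seg2d(rep$models$seg2d, ca$image)
  expect_equal(dim(pr), c(dim(ca$image$voxels), 5L))
  sums <- apply(pr, 1:3, sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_true(all(pr >= 0))
  # argmax labels are valid and ties break toward the lower class code
  labs <- infarctseg:::argmax_labels(pr)
  expect_true(all(labs %in% 0:4))
  tie <- array(0.2, c(1, 1, 1, 5))
  expect_equal(as.integer(infarctseg:::argmax_labels(tie)), 0L)
})

test_that("2D training improves with iterations and is deterministic", {
  cases <- lapply(generate_dataset(small_params(seed = 41), 3), crop_case)
  short <- train_seg2d(cases, seg2d_config(maxit = 5L, samples_per_case = 400L,
                                           seed = 7L))
  long <- train_seg2d(cases, seg2d_config(maxit = 60L, samples_per_case = 400L,
                                          seed = 7L))
  expect_lt(long$final_loss, short$final_loss)
  again <- train_seg2d(cases, seg2d_config(maxit = 5L, samples_per_case = 400L,
                                           seed = 7L))
  expect_identical(short$final_loss, again$final_loss)
  expect_error(train_seg2d(cases[1]), "at least 2")
})

test_that("held-out per-slice scar Dice of the 2D stage clears the bar", {
  rep <- pipeline_fixture()
  preds <- fixture_predictions()
  slice_dcs <- c()
  for (pr in preds) {
    gt <- pr$case$labels$labels
    p2 <- pr$seg2d_only$labels
    for (s in seq_len(dim(gt)[1])) {
      if (any(gt[s, , ] == 3L))
        slice_dcs <- c(slice_dcs, dice(p2[s, , ] == 3L, gt[s, , ] == 3L))
    }
  }
  expect_gte(mean(slice_dcs), 0.70)
})

test_that("mask perturbation is identity at zero probability and stays valid", {
  ca <- crop_case(generate_case(small_params(scar_probability = 1,
                                             mvo_probability_given_scar = 1), 2))
  sl <- ca$labels$labels[3, , ]
  zero <- perturb_config(p_dilate = 0, p_erode = 0, p_drop = 0, p_blob = 0,
                         p_swap = 0)
  expect_identical(perturb_mask(sl, zero, seed = 1), sl)
  # determinism under a fixed seed
  cfg <- perturb_config(seed = 99L)
  expect_identical(perturb_mask(sl, cfg), perturb_mask(sl, cfg))
  # labels always stay in {0..4} over many random draws
  for (s in 1:15) {
    out <- perturb_mask(sl, perturb_config(p_dilate = 1, p_erode = 1,
                                           p_drop = 1, p_blob = 1, p_swap = 1),
                        seed = s)
    expect_true(all(out %in% 0:4))
  }
  expect_error(perturb_config(p_drop = 2), "probabilities")
  expect_error(perturb_config(radius_range = c(0, 1)), "radii")
})

test_that("erosion with radius 1 removes a single-voxel scar component", {
  sl <- matrix(2L, 32, 32)
  sl[16, 16] <- 3L
  cfg <- perturb_config(p_dilate = 0, p_erode = 1, p_drop = 0, p_blob = 0,
                        p_swap = 0, radius_range = c(1L, 1L))
  out <- perturb_mask(sl, cfg, seed = 4)
  expect_false(any(out == 3L))
  expect_equal(out[16, 16], 2L)
  # morphology oracle: a 3x3 disc erosion of an isolated voxel is empty
  m <- sl == 3L
  er <- EBImage::erode(m * 1, EBImage::makeBrush(3, "disc")) > 0
  expect_false(any(er))
})

test_that("the corrector is near-identity on clean masks and repairs deletions", {
  rep <- pipeline_fixture()
  m3d <- rep$models$corrector
  m2d <- rep$models$seg2d
  cases <- fixture_test_cases()
  # fed unperturbed ground truth, the corrector must keep the scar
  gt_dcs <- vapply(cases[1:3], function(ca) {
    cc <- crop_case(ca)
    out <- infarctseg:::argmax_labels(
      predict_corrector(m3d, cc$image, cc$labels$labels))
    dice(out == 3L, cc$labels$labels == 3L)
  }, numeric(1))
  expect_gte(mean(gt_dcs), 0.95)
  # delete one scar-bearing slice from the 2D candidate; correction must help
  repaired <- 0; total <- 0
  for (ca in cases[1:4]) {
    cc <- crop_case(ca)
    cand <- infarctseg:::argmax_labels(predict_seg2d(m2d, cc$image))
    scar_slices <- which(apply(cc$labels$labels == 3L, 1, any))
    if (length(scar_slices) < 3) next
    s <- scar_slices[ceiling(length(scar_slices) / 2)]
    broken <- cand
    broken[s, , ][broken[s, , ] %in% c(3L, 4L)] <- 2L
    d_broken <- dice(broken == 3L, cc$labels$labels == 3L)
    fixed <- infarctseg:::argmax_labels(predict_corrector(m3d, cc$image, broken))
    d_fixed <- dice(fixed == 3L, cc$labels$labels == 3L)
    total <- total + 1
    repaired <- repaired + (d_fixed > d_broken)
  }
  expect_gt(total, 0)
  expect_equal(repaired, total)
})

test_that("corrector training is deterministic and needs enough cases", {
  cases <- lapply(generate_dataset(small_params(seed = 51), 3), crop_case)
  seg <- train_seg2d(cases, seg2d_config(maxit = 20L, samples_per_case = 400L,
                                         seed = 7L))
  cfg <- corrector_config(maxit = 10L, samples_per_case = 300L, seed = 9L)
  a <- train_corrector3d(cases, seg, perturb_config(), cfg)
  b <- train_corrector3d(cases, seg, perturb_config(), cfg)
  expect_identical(a$final_loss, b$final_loss)
  expect_error(train_corrector3d(cases[1], seg), "at least 2")
})

test_that("end-to-end prediction covers the grid, is automatic and accurate", {
  rep <- pipeline_fixture()
  preds <- fixture_predictions()
  for (pr in preds[1:3]) {
    expect_equal(dim(pr$corrected$labels), dim(pr$case$image$voxels))
    expect_true(all(pr$corrected$labels %in% 0:4))
  }
  scar_dcs <- vapply(preds, function(pr)
    dice(pr$corrected$labels == 3L, pr$case$labels$labels == 3L), numeric(1))
  expect_gte(mean(scar_dcs), 0.70)
  # correction does not systematically degrade the 2D result
  dcs_2d <- vapply(preds, function(pr)
    dice(pr$seg2d_only$labels == 3L, pr$case$labels$labels == 3L), numeric(1))
  expect_gte(mean(scar_dcs), mean(dcs_2d) - 0.02)
  # a scar-free phantom yields (almost) no predicted scar
  p0 <- rep$config$phantom
  p0$scar_probability <- 0
  clean <- generate_case(p0, 77)
  pred0 <- predict_pipeline(clean$image, rep$models$localizer,
                            rep$models$seg2d, rep$models$corrector)
  expect_lte(mask_volume_ml(pred0, class = "scar"), 0.5)
})
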