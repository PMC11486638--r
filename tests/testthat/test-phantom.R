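test_that("phantom spec enforces its invariants", {
  expect_error(phantom_spec(grid_shape = c(4, 32, 32)), "invalid spec")
  expect_error(phantom_spec(atrophy_per_year = 0.03,
                            age_range_years = c(18, 65)), "invalid spec")
  expect_error(phantom_spec(noise_sd = -1), "invalid spec")
  expect_s3_class(phantom_spec(), "phantom_spec")
})

test_that("template construction is deterministic, normalized, nonnegative", {
  spec <- tiny_spec()
  t1 <- make_template(spec)
  t2 <- make_template(spec)
  expect_identical(t1$data, t2$data)
  expect_equal(max(t1$data), 1)
  expect_true(all(t1$data >= 0))
  expect_length(attr(t1, "structures"), spec$n_structures)

  # different seed, different anatomy
  t3 <- make_template(tiny_spec(seed = 99L))
  expect_gt(max(abs(t3$data - t1$data)), 0)

  # zero structures: the empty sum
  t0 <- make_template(phantom_spec(grid_shape = c(8, 8, 8),
                                   n_structures = 0))
  expect_true(all(t0$data == 0))
})

test_that("subject sampling honours the identity and monotonicity contracts", {
  spec <- tiny_spec(subject_jitter_sd = 0, noise_sd = 0,
                    atrophy_per_year = 0)
  tpl <- make_template(spec)
  rec <- sample_subject(tpl, list(subject_id = "s1", group = "HS",
                                  age_years = 30, site = "a"), spec,
                        seed = 5)
  expect_equal(rec$volume$data, tpl$data, tolerance = 1e-15)

  # atrophy only: older subject has strictly lower mean density
  spec2 <- tiny_spec(subject_jitter_sd = 0, noise_sd = 0,
                     atrophy_per_year = 0.005)
  tpl2 <- make_template(spec2)
  v_young <- sample_subject(tpl2, list(subject_id = "s1", group = "HS",
                                       age_years = 20, site = "a"), spec2,
                            seed = 5)$volume
  v_old <- sample_subject(tpl2, list(subject_id = "s2", group = "HS",
                                     age_years = 60, site = "a"), spec2,
                          seed = 5)$volume
  expect_gt(mean(v_young$data), mean(v_old$data))
  # closed form: ratio of means equals ratio of age factors
  f <- function(a) 1 - spec2$atrophy_per_year * (a - 18)
  expect_equal(mean(v_old$data) / mean(v_young$data), f(60) / f(20),
               tolerance = 1e-12)

  # reproducibility under a fixed seed
  spec3 <- tiny_spec()
  tpl3 <- make_template(spec3)
  cov <- list(subject_id = "s1", group = "HS", age_years = 40, site = "a")
  r1 <- sample_subject(tpl3, cov, spec3, seed = 77)
  r2 <- sample_subject(tpl3, cov, spec3, seed = 77)
  expect_identical(r1$volume$data, r2$volume$data)
  expect_error(sample_subject(tpl3, list(subject_id = "s", group = "HS",
                                         age_years = 99, site = "a"),
                              spec3), "age")
})

test_that("disease application is an exact multiplicative reduction", {
  spec <- tiny_spec(noise_sd = 0, subject_jitter_sd = 0)
  tpl <- make_template(spec)
  rois <- make_roi_masks(tpl, 1, radius_mm = 5)

  # delta = 0 is the identity
  eff0 <- disease_effect(rois, reduction_fraction = 0, subject_sd = 0)
  out0 <- apply_disease(tpl, eff0, seed = 1)
  expect_equal(out0$data, tpl$data, tolerance = 1e-15)

  # hard mask, delta = 0.2: in-ROI values scaled by exactly 0.8,
  # out-of-ROI voxels bit-identical
  eff <- disease_effect(rois, reduction_fraction = 0.2, subject_sd = 0,
                        edge_softness_mm = 0)
  out <- apply_disease(tpl, eff, seed = 1)
  roi <- rois[[1]] > 0
  expect_equal(out$data[roi], 0.8 * tpl$data[roi], tolerance = 1e-12)
  expect_identical(out$data[!roi], tpl$data[!roi])

  # extreme reduction still leaves a nonnegative volume
  eff99 <- disease_effect(rois, reduction_fraction = 0.99, subject_sd = 0)
  expect_true(all(apply_disease(tpl, eff99, seed = 1)$data >= 0))

  # shape mismatch is an error
  small <- volume_grid(array(1, c(8, 8, 8)))
  expect_error(apply_disease(small, eff), "shape")
})

test_that("cohort generation counts, determinism, and ground truth", {
  spec <- tiny_spec()
  tpl <- make_template(spec)
  eff <- disease_effect(make_roi_masks(tpl, 1, 5), 0.3, 0.02)
  coh <- generate_cohort(spec, 5, eff, seed = 3)
  expect_length(coh$subjects, 10L)
  expect_equal(as.integer(table(cohort_groups(coh))), c(5L, 5L))
  expect_false(anyDuplicated(vapply(coh$subjects, function(s) s$subject_id,
                                    character(1))) > 0)
  ages <- cohort_ages(coh)
  expect_true(all(ages >= 18 & ages <= 65))
  expect_identical(coh$effect, eff)

  coh2 <- generate_cohort(spec, 5, eff, seed = 3)
  expect_identical(coh2$subjects[[7]]$volume$data,
                   coh$subjects[[7]]$volume$data)
  coh3 <- generate_cohort(spec, 5, eff, seed = 4)
  expect_gt(max(abs(coh3$subjects[[7]]$volume$data -
                    coh$subjects[[7]]$volume$data)), 0)
  expect_error(generate_cohort(spec, 1), "at least 2")
})

test_that("the injected effect is recoverable by direct statistics", {
  # the direct-statistics ceiling: group comparison at the study conditions
  # localizes the injected regions well
  spec <- phantom_spec()
  tpl <- make_template(spec)
  rois <- make_roi_masks(tpl, 2, 7)
  eff <- disease_effect(rois, 0.25, 0.05, edge_softness_mm = 2,
                        voxel_size_mm = 1.5)
  coh <- generate_cohort(spec, 30, eff, seed = 42)
  hs <- lapply(cohort_volumes(coh, "HS"), global_scale)
  sz <- lapply(cohort_volumes(coh, "SZ"), global_scale)
  tm <- two_sample_t_map(sz, hs, mask = tpl$data > 0.05, contrast = "A<B")
  th <- threshold_map(tm, 0.001, 10)
  roi_union <- (Reduce(pmax, rois) > 0.5) * 1
  expect_gte(dice_overlap(th$mask, roi_union), 0.5)
})

test_that("mean density regressed on age recovers the atrophy slope", {
  spec <- tiny_spec(noise_sd = 0.002, subject_jitter_sd = 0.01,
                    atrophy_per_year = 0.004)
  coh <- generate_cohort(spec, 20, effect = NULL, seed = 12)
  tpl <- make_template(spec)
  m <- vapply(cohort_volumes(coh), function(v) mean(v$data), numeric(1))
  a <- cohort_ages(coh)
  slope <- coef(lm(m ~ a))[["a"]]
  expected <- -spec$atrophy_per_year * mean(tpl$data)
  expect_lt(abs(slope - expected) / abs(expected), 0.2)
})

test_that("cohorts round-trip through the on-disk layout", {
  spec <- tiny_spec()
  tpl <- make_template(spec)
  eff <- disease_effect(make_roi_masks(tpl, 1, 5), 0.3)
  coh <- generate_cohort(spec, 2, eff, seed = 8)
  dir <- tempfile("cohort")
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "participants.tsv")))
  expect_true(file.exists(file.path(dir, "ground_truth_roi.nii.gz")))
  cov <- read_covariates(file.path(dir, "participants.tsv"))
  expect_equal(nrow(cov), 4L)
  v <- read_volume(file.path(dir, "sub-001.nii.gz"))
  expect_equal(v$data, coh$subjects[[1]]$volume$data, tolerance = 1e-7)
  expect_equal(v$voxel_size_mm, spec$voxel_size_mm)
})
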