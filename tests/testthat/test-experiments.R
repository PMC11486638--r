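# a small, fast configuration exercising the full pipelines end to end
fast_config <- function(...) {
  cfg <- experiment_config(
    phantom = list(grid_shape = c(16L, 16L, 16L), n_structures = 4L,
                   structure_smoothness_mm = 3, seed = 2L),
    effect = list(n_roi = 1L, radius_mm = 5),
    cohort = list(n_per_group = 6L),
    model = list(n_encode_blocks = 2L, n_resblocks = 1L, base_channels = 4L,
                 disc_blocks = 3L, disc_base_channels = 4L),
    train = list(epochs = 2L),
    probe = list(k = 3L)
  )
  over <- list(...)
  for (nm in names(over))
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
  cfg
}

test_that("recovery reports are complete, deterministic, and written to disk", {
  cfg <- fast_config()
  out1 <- tempfile("rec")
  rep1 <- run_recovery(cfg, seed = 4, out_dir = out1, keep_model = TRUE)
  expect_s3_class(rep1, "experiment_report")
  s <- rep1$summary
  expect_true(all(c("suprathreshold_voxels", "dice_vs_injected",
                    "roi_mean_change", "probe") %in% names(s)))
  expect_true(is.finite(s$dice_vs_injected))
  expect_gte(s$probe$p_value, 0)

  # artifacts on disk: report JSON validates, manifest files exist
  expect_true(file.exists(file.path(out1, "report.json")))
  js <- jsonlite::read_json(file.path(out1, "report.json"))
  expect_equal(js$experiment, "recovery")
  expect_equal(js$seed, 4L)
  for (f in js$manifest) expect_true(file.exists(file.path(out1, f)))

  # end-to-end determinism: identical config + seed, identical numbers
  rep2 <- run_recovery(cfg, seed = 4, keep_model = FALSE)
  expect_identical(rep1$summary, rep2$summary)
  # a different seed changes the cohort and the numbers
  rep3 <- run_recovery(cfg, seed = 5, keep_model = FALSE)
  expect_false(identical(rep1$summary$suprathreshold_voxels,
                         rep3$summary$suprathreshold_voxels) &&
               identical(rep1$summary$probe, rep3$summary$probe))
})

test_that("a null-effect recovery is calibrated and reports no truth overlap", {
  cfg <- fast_config(effect = list(reduction_fraction = 0))
  rep <- run_recovery(cfg, seed = 11, keep_model = FALSE, model =
                        identity_model(c(16, 16, 16), 1.5))
  # identity transform of a null cohort: paired differences are exactly zero
  expect_equal(rep$summary$suprathreshold_voxels, 0L)
  expect_true(is.na(rep$summary$dice_vs_injected))
})

test_that("progression with the identity generator has zero extent at every k", {
  cfg <- fast_config()
  spec <- cyclemorph:::config_phantom_spec(cfg, 3)
  tpl <- make_template(spec)
  eff <- cyclemorph:::config_effect(cfg, tpl)
  coh <- generate_cohort(spec, 4, eff, seed = 3)
  id <- identity_model(c(16, 16, 16), 1.5)
  rep <- run_progression(id, coh, n_iterations = 3, config = cfg, seed = 3)
  expect_identical(rep$summary$extent_by_iteration, rep(0L, 3L))
  # identical states across iterations: ANOVA F = 0
  expect_equal(rep$summary$age_anova$statistic, 0)
  expect_error(run_progression(id, coh, n_iterations = 1, config = cfg),
               "at least 2")
})

test_that("comorbidity self-comparison control is a calibrated null", {
  cfg <- fast_config()
  fx <- run_recovery(cfg, seed = 21, keep_model = TRUE)
  spec <- cyclemorph:::config_phantom_spec(cfg, 21)
  # dataset 2 = the training pair's healthy group relabeled, no baseline
  # effect: the virtual-vs-virtual comparison is a self-comparison of two
  # same-distribution groups and should sit near the nominal alpha level
  ds2 <- generate_cohort(spec, 6, effect = NULL,
                         group_labels = c("TD", "ASD"), seed = 22)
  rep <- run_comorbidity(fx$model, ds2, cfg,
                         trained_effect = NULL, seed = 21)
  frac <- rep$summary$twosample_suprathreshold / rep$summary$support_voxels
  expect_lt(frac, 0.02)
  # grid mismatch is rejected
  spec_big <- phantom_spec(grid_shape = c(32, 32, 32))
  ds_big <- generate_cohort(spec_big, 3, seed = 1)
  expect_error(run_comorbidity(fx$model, ds_big, cfg), "grid shape")
})
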