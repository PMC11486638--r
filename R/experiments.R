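#' Default configuration for the phantom experiments
#'
#' Returns the nested configuration list used by [run_recovery()],
#' [run_comorbidity()], and [run_progression()]: phantom conditions, injected
#' effect, model architecture, training schedule, and statistical thresholds.
#' Any element can be overridden through `...` by passing a named nested
#' list (e.g. `effect = list(reduction_fraction = 0)`).
#'
#' @param ... named sections to override (`phantom`, `effect`, `model`,
#'   `train`, `stats`, `probe`).
#' @return A nested configuration list.
#' @export
experiment_config <- function(...) {
  cfg <- list(
    phantom = list(grid_shape = c(32L, 32L, 32L), voxel_size_mm = 1.5,
                   n_structures = 8L, structure_smoothness_mm = 4,
                   subject_jitter_sd = 0.05, noise_sd = 0.02,
                   noise_smoothness_mm = 0, age_range_years = c(18, 65),
                   atrophy_per_year = 0.004, seed = 1L),
    effect = list(n_roi = 2L, radius_mm = 7, reduction_fraction = 0.25,
                  subject_sd = 0.05, edge_softness_mm = 2),
    cohort = list(n_per_group = 30L, group_labels = c("HS", "SZ")),
    model = list(n_encode_blocks = 3L, n_resblocks = 6L, base_channels = 8L,
                 disc_blocks = 4L, disc_base_channels = 8L,
                 final_activation = "tanh"),
    train = list(epochs = 12L, lambda_cycle = 10, learning_rate = 2e-4,
                 betas = c(0.5, 0.999), saturating = FALSE),
    stats = list(p_voxel = 0.001, min_cluster_size = 10L, global_mean = 50,
                 support_threshold = 0.05),
    probe = list(k = 5L)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config section: ", nm)
    cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
  }
  cfg
}

config_phantom_spec <- function(cfg, seed) {
  p <- cfg$phantom
  phantom_spec(grid_shape = p$grid_shape, voxel_size_mm = p$voxel_size_mm,
               n_structures = p$n_structures,
               structure_smoothness_mm = p$structure_smoothness_mm,
               subject_jitter_sd = p$subject_jitter_sd, noise_sd = p$noise_sd,
               noise_smoothness_mm = p$noise_smoothness_mm,
               age_range_years = p$age_range_years,
               atrophy_per_year = p$atrophy_per_year,
               seed = if (is.null(seed)) p$seed else p$seed)
}

config_effect <- function(cfg, template) {
  e <- cfg$effect
  if (!is.null(e$reduction_fraction) && e$reduction_fraction == 0)
    return(NULL)
  rois <- make_roi_masks(template, n_roi = e$n_roi, radius_mm = e$radius_mm)
  disease_effect(rois, reduction_fraction = e$reduction_fraction,
                 subject_sd = e$subject_sd,
                 edge_softness_mm = e$edge_softness_mm,
                 voxel_size_mm = cfg$phantom$voxel_size_mm)
}

config_model_fit <- function(cfg, domain_a, domain_b, seed) {
  m <- cfg$model; tr <- cfg$train
  cyclegan(domain_a, domain_b,
           gen_config = generator_config(
             n_encode_blocks = m$n_encode_blocks,
             n_decode_blocks = m$n_encode_blocks,
             n_resblocks = m$n_resblocks, base_channels = m$base_channels,
             final_activation = m$final_activation),
           disc_config = discriminator_config(
             n_blocks = m$disc_blocks,
             base_channels = m$disc_base_channels),
           lambda_cycle = tr$lambda_cycle, epochs = tr$epochs,
           learning_rate = tr$learning_rate, betas = tr$betas,
           saturating = tr$saturating, seed = seed)
}

# Global scaling within the anatomy support: generated volumes carry a tiny
# nonzero background (tanh output), which would dominate the default mean/8
# mask on mostly-empty phantom grids.
scale_all <- function(vols, target, mask = NULL)
  lapply(vols, global_scale, target_mean = target, mask = mask)

roi_union_mask <- function(effect) {
  if (is.null(effect)) return(NULL)
  (Reduce(pmax, effect$roi_masks) > 0.5) * 1
}

#' Effect-recovery experiment
#'
#' The first validation: generate a two-group phantom cohort with a known
#' injected effect, train the translation model on the two groups, transform
#' the healthy group into its "virtual disease" state, and test whether
#' voxel-wise paired statistics between original and virtual volumes recover
#' the injected regions. Also runs the covariate probe (cross-validated age
#' prediction pre vs post transformation).
#'
#' @param config an [experiment_config()].
#' @param seed master seed for cohort sampling and training.
#' @param out_dir optional directory; when given, NIfTI maps, tables, the
#'   report JSON, and a manifest are written there.
#' @param model optional pre-trained [cyclegan()] to reuse (skips training).
#' @param keep_model keep the fitted model in the returned report.
#' @return An `experiment_report` list: suprathreshold extent, cluster
#'   table, Dice against the injected ROI union, mean in-ROI change,
#'   covariate-probe statistics, loss history summary.
#' @export
run_recovery <- function(config = experiment_config(), seed = 1L,
                         out_dir = NULL, model = NULL, keep_model = TRUE) {
  spec <- config_phantom_spec(config, seed)
  template <- make_template(spec)
  effect <- config_effect(config, template)
  cohort <- generate_cohort(spec, config$cohort$n_per_group, effect,
                            group_labels = config$cohort$group_labels,
                            seed = seed)
  labs <- config$cohort$group_labels
  hs <- cohort_volumes(cohort, labs[1])
  dz <- cohort_volumes(cohort, labs[2])
  if (is.null(model)) model <- config_model_fit(config, hs, dz, seed)
  virt <- predict(model, hs, direction = "a2b")

  st <- config$stats
  support <- template$data > st$support_threshold
  pre <- scale_all(hs, st$global_mean, support)
  post <- scale_all(virt, st$global_mean, support)
  tm <- paired_t_map(pre, post, mask = support, contrast = "post<pre")
  roi <- roi_union_mask(effect)
  rois_list <- if (is.null(roi)) NULL else list(injected = roi)
  th <- threshold_map(tm, st$p_voxel, st$min_cluster_size, rois = rois_list)
  dice <- if (is.null(roi)) NA_real_ else dice_overlap(th$mask, roi)
  roi_change <- if (is.null(roi)) NA_real_ else
    mean(vapply(seq_along(pre), function(i)
      mean(post[[i]]$data[roi > 0]) - mean(pre[[i]]$data[roi > 0]),
      numeric(1)))

  ages <- cohort_ages(cohort, labs[1])
  ids <- vapply(cohort_subjects(cohort, labs[1]),
                function(s) s$subject_id, character(1))
  # the probe runs on unscaled volumes: proportional global scaling would
  # divide out the age-related density gradient it is meant to detect
  pr_pre <- predict_age_cv(list(volumes = hs, ages = ages,
                                subject_ids = ids),
                           k = config$probe$k, seed = seed,
                           state = "original")
  pr_post <- predict_age_cv(list(volumes = virt, ages = ages,
                                 subject_ids = ids),
                            k = config$probe$k, seed = seed,
                            state = "virtual")
  probe <- compare_predictions_paired(pr_pre, pr_post)

  report <- new_report("recovery", config, seed, list(
    n_per_group = config$cohort$n_per_group,
    support_voxels = sum(support),
    suprathreshold_voxels = sum(th$mask),
    suprathreshold_fraction = sum(th$mask) / sum(support),
    n_clusters = nrow(th$table),
    dice_vs_injected = dice,
    roi_mean_change = roi_change,
    probe = comparison_as_list(probe),
    age_mae_original = pr_pre$mae,
    age_mae_virtual = pr_post$mae,
    final_losses = as.list(model$loss_history[nrow(model$loss_history), ])
  ))
  report$stat_map <- tm
  report$thresholded <- th
  report$cluster_table <- th$table
  report$age_predictions <- list(original = pr_pre, virtual = pr_post)
  if (keep_model) report$model <- model
  if (!is.null(out_dir))
    write_report(report, out_dir, maps = list(recovery = list(tm, th)),
                 voxel_size_mm = spec$voxel_size_mm, stats = st)
  report
}

#' Comorbidity-composition experiment
#'
#' Applies a generator trained on one dataset pair (e.g. a
#' healthy-vs-disease cohort) to a second, independent cohort that carries
#' its own baseline effect, producing four states: the two originals and the
#' two "virtual comorbid" states. Two comparisons are reported: (i) paired,
#' baseline-disease originals vs their virtual comorbid versions (should
#' recover the trained effect regions regardless of baseline); and (ii)
#' two-sample, virtual control+disease vs virtual baseline+disease (the
#' baseline effect should persist through transformation).
#'
#' @param model a fitted [cyclegan()] (trained on dataset 1).
#' @param dataset_2 a `cohort` whose second group carries the baseline
#'   effect (its ground truth is read from the cohort).
#' @param config an [experiment_config()] (statistics settings are used).
#' @param trained_effect optional `disease_effect` of the training pair, for
#'   Dice scoring of comparison (i).
#' @param seed seed for the probe folds.
#' @param out_dir optional output directory.
#' @return An `experiment_report` with both comparisons.
#' @export
run_comorbidity <- function(model, dataset_2, config = experiment_config(),
                            trained_effect = NULL, seed = 1L,
                            out_dir = NULL) {
  stopifnot(inherits(model, "cyclegan"), inherits(dataset_2, "cohort"))
  if (!all(dataset_2$spec$grid_shape == model$input_shape))
    stop("dataset_2 grid shape does not match the model")
  labs <- dataset_2$group_labels
  td <- cohort_volumes(dataset_2, labs[1])
  asd <- cohort_volumes(dataset_2, labs[2])
  v_td <- predict(model, td, direction = "a2b")    # virtual control+disease
  v_asd <- predict(model, asd, direction = "a2b")  # virtual baseline+disease

  st <- config$stats
  support <- dataset_2$template$data > st$support_threshold
  s_asd <- scale_all(asd, st$global_mean, support)
  s_vasd <- scale_all(v_asd, st$global_mean, support)
  s_vtd <- scale_all(v_td, st$global_mean, support)

  trained_roi <- roi_union_mask(trained_effect)
  baseline_roi <- roi_union_mask(dataset_2$effect)

  # (i) paired: baseline originals vs virtual comorbid
  tm1 <- paired_t_map(s_asd, s_vasd, mask = support, contrast = "post<pre")
  rois1 <- if (is.null(trained_roi)) NULL else list(trained = trained_roi)
  th1 <- threshold_map(tm1, st$p_voxel, st$min_cluster_size, rois = rois1)
  dice1 <- if (is.null(trained_roi)) NA_real_
           else dice_overlap(th1$mask, trained_roi)

  # (ii) two-sample: virtual control+disease vs virtual baseline+disease
  tm2 <- two_sample_t_map(s_vtd, s_vasd, mask = support,
                          contrast = "two-sided")
  rois2 <- if (is.null(baseline_roi)) NULL else list(baseline = baseline_roi)
  th2 <- threshold_map(tm2, st$p_voxel, st$min_cluster_size, rois = rois2)
  dice2 <- if (is.null(baseline_roi)) NA_real_
           else dice_overlap(th2$mask, baseline_roi)

  report <- new_report("comorbidity", config, seed, list(
    n_control = length(td), n_baseline = length(asd),
    support_voxels = sum(support),
    paired_suprathreshold = sum(th1$mask),
    paired_dice_vs_trained_roi = dice1,
    twosample_suprathreshold = sum(th2$mask),
    twosample_dice_vs_baseline_roi = dice2
  ))
  report$comparisons <- list(
    paired_baseline_vs_virtual = list(map = tm1, thresholded = th1),
    virtual_vs_virtual = list(map = tm2, thresholded = th2))
  if (!is.null(out_dir))
    write_report(report, out_dir,
                 maps = list(paired = list(tm1, th1),
                             twosample = list(tm2, th2)),
                 voxel_size_mm = dataset_2$spec$voxel_size_mm, stats = st)
  report
}

#' Iterated-progression experiment
#'
#' Applies the trained generator repeatedly (1..n_iterations) to the healthy
#' group and, for each iteration count, compares the iterated state against
#' the originals with a paired t-map, tracking the suprathreshold extent
#' (voxel count within the template support). Progressive expansion of the
#' extent emulates disease progression. Age predictions are computed per
#' state and compared across iterations with a one-way ANOVA (individual
#' characteristics should be preserved, so no significant differences are
#' expected when disease and age are orthogonal).
#'
#' @param model a fitted [cyclegan()].
#' @param cohort the phantom cohort whose healthy group is iterated.
#' @param n_iterations number of repeated transformations (>= 2).
#' @param config an [experiment_config()].
#' @param seed probe-fold seed.
#' @param out_dir optional output directory.
#' @return An `experiment_report` with the extent curve and the ANOVA.
#' @export
run_progression <- function(model, cohort, n_iterations = 5L,
                            config = experiment_config(), seed = 1L,
                            out_dir = NULL) {
  stopifnot(inherits(model, "cyclegan"), inherits(cohort, "cohort"))
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 2L) stop("`n_iterations` must be at least 2")
  labs <- cohort$group_labels
  hs <- cohort_volumes(cohort, labs[1])
  iters <- lapply(hs, iterate_transform, model = model, direction = "a2b",
                  n_iterations = n_iterations)

  st <- config$stats
  support <- cohort$template$data > st$support_threshold
  pre <- scale_all(hs, st$global_mean, support)
  ages <- cohort_ages(cohort, labs[1])
  ids <- vapply(cohort_subjects(cohort, labs[1]),
                function(s) s$subject_id, character(1))

  extent <- integer(n_iterations)
  maps <- vector("list", n_iterations)
  preds <- vector("list", n_iterations + 1L)
  preds[[1]] <- predict_age_cv(list(volumes = hs, ages = ages,
                                    subject_ids = ids),
                               k = config$probe$k, seed = seed,
                               state = "original")
  for (k in seq_len(n_iterations)) {
    state_k <- scale_all(lapply(iters, `[[`, k), st$global_mean, support)
    tmk <- paired_t_map(pre, state_k, mask = support, contrast = "post<pre")
    thk <- threshold_map(tmk, st$p_voxel, st$min_cluster_size)
    extent[k] <- as.integer(sum(thk$mask))
    maps[[k]] <- list(map = tmk, thresholded = thk)
    preds[[k + 1L]] <- predict_age_cv(
      list(volumes = lapply(iters, `[[`, k), ages = ages,
           subject_ids = ids),
      k = config$probe$k, seed = seed, state = paste0("iteration-", k))
  }
  aov_stats <- compare_predictions_anova(preds)

  report <- new_report("progression", config, seed, list(
    n_iterations = n_iterations,
    extent_by_iteration = extent,
    extent_expansion = extent[n_iterations] - extent[1],
    age_anova = comparison_as_list(aov_stats),
    age_mae_by_state = vapply(preds, function(p) p$mae, numeric(1))
  ))
  report$maps <- maps
  report$age_predictions <- preds
  if (!is.null(out_dir)) {
    ml <- stats::setNames(
      lapply(seq_len(n_iterations),
             function(k) list(maps[[k]]$map, maps[[k]]$thresholded)),
      paste0("iteration-", seq_len(n_iterations)))
    write_report(report, out_dir, maps = ml,
                 voxel_size_mm = cohort$spec$voxel_size_mm, stats = st)
  }
  report
}

new_report <- function(experiment, config, seed, summary) {
  structure(list(experiment = experiment, config = config, seed = seed,
                 summary = summary,
                 package_version =
                   as.character(utils::packageVersion("cyclemorph"))),
            class = "experiment_report")
}

comparison_as_list <- function(x) {
  list(test = x$test, statistic = x$statistic, p_value = x$p_value,
       effect_size = x$effect_size, effect_type = x$effect_type)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report> ", x$experiment, " (seed ", x$seed, ")\n",
      sep = "")
  s <- x$summary
  for (nm in names(s)) {
    v <- s[[nm]]
    if (is.list(v))
      cat("  ", nm, ": ",
          paste(sprintf("%s=%.4g", names(unlist(v)),
                        suppressWarnings(as.numeric(unlist(v)))),
                collapse = ", "), "\n", sep = "")
    else cat("  ", nm, ": ", paste(format(v, digits = 4), collapse = " "),
             "\n", sep = "")
  }
  invisible(x)
}

# Write report JSON + NIfTI maps + cluster TSVs + manifest into `dir`.
write_report <- function(report, dir, maps = NULL, voxel_size_mm = 1.5,
                         stats = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  if (!is.null(maps)) {
    for (nm in names(maps)) {
      write_stat_map(maps[[nm]][[1]], maps[[nm]][[2]], dir, prefix = nm,
                     voxel_size_mm = voxel_size_mm,
                     p_voxel = stats$p_voxel %||% 0.001,
                     min_cluster_size = stats$min_cluster_size %||% 10L)
      files <- c(files, paste0(nm, c("_tmap.nii.gz", "_mask.nii.gz",
                                     "_clusters.tsv", "_sidecar.json")))
    }
  }
  payload <- list(experiment = report$experiment, seed = report$seed,
                  package_version = report$package_version,
                  config = report$config, summary = report$summary,
                  manifest = files)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  write_manifest(dir, inputs = files, config = report$config,
                 seed = report$seed)
  invisible(dir)
}
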