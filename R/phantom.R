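#' Specification of a synthetic gray-matter phantom
#'
#' Defines the study conditions for a synthetic two-group cohort of 3D
#' gray-matter density maps. A phantom "anatomy" is a sum of smoothed
#' ellipsoidal structures; each subject perturbs the structure amplitudes
#' (anatomical variability), loses density globally with age (atrophy
#' gradient), and receives additive voxel noise.
#'
#' @param grid_shape integer vector of 3 extents (each >= 8 voxels).
#' @param voxel_size_mm isotropic voxel size, mm.
#' @param n_structures number of ellipsoidal structures in the template.
#' @param structure_smoothness_mm FWHM of the smoothing applied to each
#'   structure indicator, mm.
#' @param subject_jitter_sd per-subject, per-structure fractional amplitude
#'   standard deviation (anatomical variability).
#' @param noise_sd standard deviation of additive voxel noise (density
#'   units).
#' @param noise_smoothness_mm FWHM of optional smoothing of the noise field;
#'   0 (the default) keeps voxel noise independent, which makes voxel-wise
#'   test calibration exact.
#' @param age_range_years numeric `c(low, high)` of the uniform age
#'   distribution.
#' @param atrophy_per_year fractional global density loss per year of age;
#'   must satisfy `atrophy_per_year * diff(age_range_years) < 1`.
#' @param seed integer seed controlling the template anatomy.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 32L), voxel_size_mm = 1.5,
                         n_structures = 8L, structure_smoothness_mm = 4,
                         subject_jitter_sd = 0.05, noise_sd = 0.02,
                         noise_smoothness_mm = 0,
                         age_range_years = c(18, 65),
                         atrophy_per_year = 0.004, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("invalid spec: `grid_shape` must be 3 integers, each >= 8")
  if (voxel_size_mm <= 0) stop("invalid spec: `voxel_size_mm` must be > 0")
  if (n_structures < 0) stop("invalid spec: `n_structures` must be >= 0")
  if (structure_smoothness_mm <= 0)
    stop("invalid spec: `structure_smoothness_mm` must be > 0")
  if (subject_jitter_sd < 0 || noise_sd < 0 || noise_smoothness_mm < 0)
    stop("invalid spec: dispersion parameters must be nonnegative")
  age_range_years <- as.numeric(age_range_years)
  if (length(age_range_years) != 2L ||
      age_range_years[2] <= age_range_years[1])
    stop("invalid spec: `age_range_years` must be (low, high) with low < high")
  if (atrophy_per_year < 0)
    stop("invalid spec: `atrophy_per_year` must be nonnegative")
  if (atrophy_per_year * diff(age_range_years) >= 1)
    stop("invalid spec: atrophy over the age range reaches 100% density loss")
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 n_structures = as.integer(n_structures),
                 structure_smoothness_mm = structure_smoothness_mm,
                 subject_jitter_sd = subject_jitter_sd, noise_sd = noise_sd,
                 noise_smoothness_mm = noise_smoothness_mm,
                 age_range_years = age_range_years,
                 atrophy_per_year = atrophy_per_year, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Build the phantom anatomy template
#'
#' Sums `n_structures` smoothed ellipsoid indicator fields placed at seeded
#' random positions, then peak-normalizes the sum to a maximum of 1. The
#' per-structure fields are kept as an attribute so that subject-level
#' amplitude jitter can be applied structure by structure.
#'
#' @param spec a [phantom_spec()].
#' @return A [volume_grid()] with attributes `structures` (list of arrays),
#'   `centers` (matrix of voxel coordinates), and `spec`.
#' @export
make_template <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  with_seed(spec$seed, {
    fields <- vector("list", spec$n_structures)
    centers <- matrix(NA_real_, spec$n_structures, 3L)
    sigma <- fwhm_sigma_voxels(spec$structure_smoothness_mm,
                               spec$voxel_size_mm)
    ax <- lapply(1:3, function(i) seq_len(d[i]))
    for (s in seq_len(spec$n_structures)) {
      ctr <- vapply(1:3, function(i) stats::runif(1, 0.28 * d[i], 0.72 * d[i]),
                    numeric(1))
      rad <- vapply(1:3, function(i) stats::runif(1, 0.10 * d[i], 0.22 * d[i]),
                    numeric(1))
      blob <- ellipsoid_indicator(d, ctr, rad)
      fields[[s]] <- smooth_array_gaussian(blob, sigma)
      centers[s, ] <- ctr
    }
    total <- array(0, dim = d)
    for (f in fields) total <- total + f
    peak <- max(total)
    if (peak > 0) {
      total <- total / peak
      fields <- lapply(fields, function(f) f / peak)
    }
    out <- volume_grid(total, spec$voxel_size_mm)
    attr(out, "structures") <- fields
    attr(out, "centers") <- centers
    attr(out, "spec") <- spec
    out
  })
}

ellipsoid_indicator <- function(d, ctr, rad) {
  x1 <- ((seq_len(d[1]) - ctr[1]) / rad[1])^2
  x2 <- ((seq_len(d[2]) - ctr[2]) / rad[2])^2
  x3 <- ((seq_len(d[3]) - ctr[3]) / rad[3])^2
  q <- outer(outer(x1, x2, `+`), x3, `+`)
  array(as.numeric(q <= 1), dim = d)
}

#' Sample one phantom subject
#'
#' The subject volume is the template scaled by an age factor
#' `1 - atrophy_per_year * (age - age_low)`, with per-structure amplitude
#' jitter and additive voxel noise, clipped at zero. When
#' `atrophy_per_year > 0` the expected density is strictly decreasing in
#' age.
#'
#' @param template the [make_template()] output.
#' @param covariates list with `subject_id`, `group`, `age_years`, `site`,
#'   and optionally `provenance` (default "real").
#' @param spec the [phantom_spec()].
#' @param seed optional integer; when given, sampling runs in an isolated
#'   seeded RNG stream, otherwise the current stream is consumed.
#' @return A `subject_record`: the covariates plus a `volume`.
#' @export
sample_subject <- function(template, covariates, spec, seed = NULL) {
  stopifnot(is_volume_grid(template), inherits(spec, "phantom_spec"))
  age <- covariates$age_years
  if (age < spec$age_range_years[1] || age > spec$age_range_years[2])
    stop("subject age ", age, " outside the spec age range")
  draw <- function() {
    fields <- attr(template, "structures")
    base <- array(0, dim = spec$grid_shape)
    if (length(fields)) {
      jit <- 1 + stats::rnorm(length(fields), 0, spec$subject_jitter_sd)
      for (s in seq_along(fields)) base <- base + jit[s] * fields[[s]]
    }
    agef <- 1 - spec$atrophy_per_year * (age - spec$age_range_years[1])
    vol <- base * agef
    if (spec$noise_sd > 0) {
      noise <- array(stats::rnorm(prod(spec$grid_shape), 0, spec$noise_sd),
                     dim = spec$grid_shape)
      if (spec$noise_smoothness_mm > 0)
        noise <- smooth_array_gaussian(
          noise, fwhm_sigma_voxels(spec$noise_smoothness_mm,
                                   spec$voxel_size_mm))
      # noise lives on the anatomy only: modulated gray-matter maps are
      # exactly zero outside tissue, and a noisy background would dominate
      # the SPM-style global (mean/8) mask on mostly-empty grids
      vol <- vol + noise * (template$data > 0.01)
    }
    pmax(vol, 0)
  }
  dat <- if (is.null(seed)) draw() else with_seed(seed, draw())
  rec <- list(subject_id = covariates$subject_id, group = covariates$group,
              age_years = age, site = covariates$site %||% "site1",
              provenance = covariates$provenance %||% "real",
              volume = volume_grid(dat, spec$voxel_size_mm))
  class(rec) <- "subject_record"
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Describe an injected regional disease effect
#'
#' A multiplicative density reduction inside a union of regions of interest,
#' matching the volume-reduction semantics of modulated gray-matter maps: a
#' subject with reduction `delta` keeps a fraction `1 - delta` of density
#' inside the (optionally edge-softened) ROI mask.
#'
#' @param roi_masks list of binary 3D arrays (or [volume_grid()]s), each with
#'   at least one voxel set.
#' @param reduction_fraction mean reduction `delta` in `[0, 1)`.
#' @param subject_sd per-subject standard deviation of `delta`; draws are
#'   truncated to `[0, 1)`.
#' @param edge_softness_mm FWHM of smoothing applied to the mask union
#'   boundary (0 = hard mask).
#' @param voxel_size_mm voxel size used to convert `edge_softness_mm`.
#' @return An object of class `disease_effect` with the softened union mask
#'   precomputed in `$mask`.
#' @export
disease_effect <- function(roi_masks, reduction_fraction = 0.25,
                           subject_sd = 0.05, edge_softness_mm = 0,
                           voxel_size_mm = 1.5) {
  if (!length(roi_masks)) stop("`roi_masks` must contain at least one mask")
  roi_masks <- lapply(roi_masks, function(m) {
    if (is_volume_grid(m)) m <- m$data
    if (!is.array(m) || length(dim(m)) != 3L)
      stop("each ROI mask must be a 3D array")
    storage.mode(m) <- "double"
    if (!all(m %in% c(0, 1))) stop("ROI masks must be binary")
    m
  })
  d <- dim(roi_masks[[1]])
  for (m in roi_masks) if (!all(dim(m) == d)) stop("ROI mask shapes differ")
  union <- Reduce(pmax, roi_masks)
  if (sum(union) == 0) stop("ROI union is empty")
  if (reduction_fraction < 0 || reduction_fraction >= 1)
    stop("`reduction_fraction` must be in [0, 1)")
  if (subject_sd < 0) stop("`subject_sd` must be nonnegative")
  soft <- union
  if (edge_softness_mm > 0)
    soft <- smooth_array_gaussian(
      union, fwhm_sigma_voxels(edge_softness_mm, voxel_size_mm))
  structure(list(roi_masks = roi_masks, reduction_fraction = reduction_fraction,
                 subject_sd = subject_sd, edge_softness_mm = edge_softness_mm,
                 mask = soft),
            class = "disease_effect")
}

#' Build spherical ROI masks centred on template structures
#'
#' Convenience constructor for ground-truth regions: spheres of radius
#' `radius_mm` centred on the first `n_roi` structure centres of a phantom
#' template, so the injected effect always sits inside tissue.
#'
#' @param template the [make_template()] output.
#' @param n_roi number of ROIs.
#' @param radius_mm sphere radius, mm.
#' @return A list of binary arrays.
#' @export
make_roi_masks <- function(template, n_roi = 2L, radius_mm = 7) {
  centers <- attr(template, "centers")
  spec <- attr(template, "spec")
  if (is.null(centers) || nrow(centers) < n_roi)
    stop("template has fewer than ", n_roi, " structures")
  d <- dim(template$data)
  r_vox <- radius_mm / spec$voxel_size_mm
  lapply(seq_len(n_roi), function(s)
    ellipsoid_indicator(d, centers[s, ], rep(r_vox, 3L)))
}

#' Apply a disease effect to one volume
#'
#' Inside the softened mask `M` the density becomes
#' `v * (1 - delta_s * M)`; outside it is unchanged. The per-subject
#' reduction `delta_s` is drawn once per call from a normal truncated to
#' `[0, 1)`.
#'
#' @param volume a [volume_grid()].
#' @param effect a [disease_effect()].
#' @param seed optional integer for an isolated seeded draw of `delta_s`.
#' @return The affected [volume_grid()] (attribute `delta` records the draw).
#' @export
apply_disease <- function(volume, effect, seed = NULL) {
  stopifnot(is_volume_grid(volume), inherits(effect, "disease_effect"))
  if (!all(dim(volume$data) == dim(effect$mask)))
    stop("ROI mask shape does not match the volume")
  draw <- function() rtrunc_norm01(effect$reduction_fraction, effect$subject_sd)
  delta <- if (is.null(seed)) draw() else with_seed(seed, draw())
  volume$data <- pmax(volume$data * (1 - delta * effect$mask), 0)
  attr(volume, "delta") <- delta
  volume
}

# normal truncated to [0, 1) by rejection; sd = 0 degenerates to the mean
rtrunc_norm01 <- function(mean, sd) {
  if (sd == 0) return(min(max(mean, 0), 1 - 1e-12))
  for (i in 1:10000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= 0 && x < 1) return(x)
  }
  stop("truncated-normal rejection sampling failed")
}

#' Generate a two-group phantom cohort
#'
#' Samples `2 * n_per_group` subjects on a shared template. Ages are sampled
#' uniformly over the spec range independently of group, so age and disease
#' are orthogonal by construction. The second group receives the disease
#' effect; the ground truth is stored in the returned cohort.
#'
#' @param spec a [phantom_spec()].
#' @param n_per_group subjects per group (>= 2).
#' @param effect optional [disease_effect()] applied to the second group.
#' @param group_labels character pair, default `c("HS", "SZ")`.
#' @param site site label for all subjects.
#' @param seed cohort-level seed (default `spec$seed`); the template anatomy
#'   is always controlled by `spec$seed`.
#' @return An object of class `cohort`.
#' @export
generate_cohort <- function(spec, n_per_group, effect = NULL,
                            group_labels = c("HS", "SZ"), site = "site1",
                            seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  n_per_group <- as.integer(n_per_group)
  if (n_per_group < 2L) stop("`n_per_group` must be at least 2")
  if (length(group_labels) != 2L) stop("`group_labels` must be a pair")
  template <- make_template(spec)
  subjects <- with_seed(seed, {
    out <- vector("list", 2L * n_per_group)
    idx <- 0L
    for (g in 1:2) {
      for (i in seq_len(n_per_group)) {
        idx <- idx + 1L
        age <- stats::runif(1, spec$age_range_years[1],
                            spec$age_range_years[2])
        rec <- sample_subject(template,
                              list(subject_id = sprintf("sub-%03d", idx),
                                   group = group_labels[g], age_years = age,
                                   site = site),
                              spec)
        if (g == 2L && !is.null(effect))
          rec$volume <- apply_disease(rec$volume, effect)
        out[[idx]] <- rec
      }
    }
    out
  })
  structure(list(subjects = subjects, spec = spec, effect = effect,
                 template = template, group_labels = group_labels),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(vapply(x$subjects, function(s) s$group, character(1)))
  cat("<cohort> ", length(x$subjects), " subjects (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ") on a ",
      paste(x$spec$grid_shape, collapse = "x"), " grid",
      if (!is.null(x$effect))
        sprintf("; injected effect delta = %.3g",
                x$effect$reduction_fraction) else "",
      "\n", sep = "")
  invisible(x)
}

#' Extract subject volumes, ages, or groups from a cohort
#'
#' @param cohort a [generate_cohort()] result (or any list of
#'   `subject_record`s wrapped in a cohort).
#' @param group optional group label filter.
#' @return `cohort_volumes`: list of [volume_grid()]s; `cohort_ages`:
#'   numeric vector; `cohort_groups`: character vector.
#' @export
cohort_volumes <- function(cohort, group = NULL) {
  subs <- cohort_subjects(cohort, group)
  lapply(subs, function(s) s$volume)
}

#' @rdname cohort_volumes
#' @export
cohort_ages <- function(cohort, group = NULL) {
  vapply(cohort_subjects(cohort, group), function(s) s$age_years, numeric(1))
}

#' @rdname cohort_volumes
#' @export
cohort_groups <- function(cohort) {
  vapply(cohort$subjects, function(s) s$group, character(1))
}

cohort_subjects <- function(cohort, group = NULL) {
  subs <- cohort$subjects
  if (!is.null(group))
    subs <- Filter(function(s) identical(s$group, group), subs)
  subs
}

#' Write a cohort to disk
#'
#' Writes one NIfTI volume per subject, a `participants.tsv` covariate table
#' (`subject_id`, `group`, `age`, `site`), and, when the cohort has an
#' injected effect, `ground_truth_roi.nii.gz` with the ROI union.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$subjects, function(s) {
    write_volume(s$volume, file.path(dir, paste0(s$subject_id, ".nii.gz")))
    data.frame(subject_id = s$subject_id, group = s$group, age = s$age_years,
               site = s$site, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, file.path(dir, "participants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$effect)) {
    roi <- volume_grid(Reduce(pmax, cohort$effect$roi_masks),
                       cohort$spec$voxel_size_mm)
    write_volume(roi, file.path(dir, "ground_truth_roi.nii.gz"))
  }
  invisible(dir)
}
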