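#' Voxel-wise paired t-map between two aligned states
#'
#' For each voxel, computes the paired t statistic of `post - pre` over
#' subjects (`t = mean(d) / (sd(d) / sqrt(n))`, `n - 1` degrees of freedom)
#' and its two-sided p-value. Voxels with zero difference variance, and
#' voxels outside the analysis mask, are `NaN`. Apply [global_scale()] to
#' every image upstream so that overall intensity offsets between states do
#' not masquerade as regional effects.
#'
#' @param pre,post lists of [volume_grid()]s (or 3D arrays) of equal length
#'   `n >= 3`, aligned subject by subject.
#' @param mask optional logical/binary array restricting the analysis.
#' @param contrast direction label stored with the map: `"post<pre"`
#'   (default; decreases are suprathreshold), `"post>pre"`, or
#'   `"two-sided"`.
#' @return A `stat_map`: list with `t`, `p` (3D arrays), `dof`, `contrast`,
#'   `analysis_mask`, `n`.
#' @export
paired_t_map <- function(pre, post, mask = NULL,
                         contrast = c("post<pre", "post>pre", "two-sided")) {
  contrast <- match.arg(contrast)
  pre_m <- stack_volumes(pre)
  post_m <- stack_volumes(post)
  if (nrow(pre_m$mat) != nrow(post_m$mat))
    stop("`pre` and `post` must contain the same number of subjects")
  n <- nrow(pre_m$mat)
  if (n < 3L) stop("need at least 3 subject pairs, got ", n)
  if (!all(pre_m$dim == post_m$dim)) stop("pre/post grid shapes differ")
  d <- post_m$mat - pre_m$mat
  m <- colMeans(d)
  v <- (colSums(d^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0  # guard tiny negative rounding
  se <- sqrt(v / n)
  t <- ifelse(se > 0, m / se, NaN)
  finish_stat_map(t, n - 1L, pre_m$dim, mask, contrast, n)
}

#' Voxel-wise two-sample t-map between two groups
#'
#' Pooled-variance two-sample t per voxel with `n_A + n_B - 2` degrees of
#' freedom; the statistic is `mean_A - mean_B` over its pooled standard
#' error, so negative t means the first group is smaller.
#'
#' @param group_a,group_b lists of volumes, each of length >= 3.
#' @param mask optional analysis mask.
#' @param contrast `"A<B"`, `"A>B"`, or `"two-sided"` (default).
#' @return A `stat_map` (see [paired_t_map()]).
#' @export
two_sample_t_map <- function(group_a, group_b, mask = NULL,
                             contrast = c("two-sided", "A<B", "A>B")) {
  contrast <- match.arg(contrast)
  A <- stack_volumes(group_a)
  B <- stack_volumes(group_b)
  if (!all(A$dim == B$dim)) stop("group grid shapes differ")
  na <- nrow(A$mat); nb <- nrow(B$mat)
  if (na < 3L || nb < 3L) stop("need at least 3 subjects per group")
  ma <- colMeans(A$mat); mb <- colMeans(B$mat)
  va <- (colSums(A$mat^2) - na * ma^2) / (na - 1)
  vb <- (colSums(B$mat^2) - nb * mb^2) / (nb - 1)
  va[va < 0] <- 0; vb[vb < 0] <- 0
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- ifelse(se > 0, (ma - mb) / se, NaN)
  finish_stat_map(t, na + nb - 2L, A$dim, mask, contrast, c(na, nb))
}

finish_stat_map <- function(t, dof, dim3, mask, contrast, n) {
  if (is.null(mask)) {
    mask_l <- rep(TRUE, length(t))
  } else {
    if (is_volume_grid(mask)) mask <- mask$data
    if (!all(dim(mask) == dim3)) stop("mask shape does not match volumes")
    mask_l <- as.logical(as.numeric(mask) != 0)
  }
  t[!mask_l] <- NaN
  p <- 2 * stats::pt(-abs(t), df = dof)
  structure(list(t = array(t, dim3), p = array(p, dim3), dof = dof,
                 contrast = contrast,
                 analysis_mask = array(mask_l, dim3), n = n),
            class = "stat_map")
}

stack_volumes <- function(vols) {
  if (inherits(vols, "cohort")) vols <- cohort_volumes(vols)
  if (!is.list(vols) || !length(vols)) stop("expected a nonempty volume list")
  arrs <- lapply(vols, function(v) if (is_volume_grid(v)) v$data else v)
  d <- dim(arrs[[1]])
  for (a in arrs) if (!all(dim(a) == d)) stop("volume shapes differ")
  list(mat = do.call(rbind, lapply(arrs, as.numeric)), dim = d)
}

#' @export
print.stat_map <- function(x, ...) {
  ok <- is.finite(x$t)
  cat(sprintf(
    "<stat_map> %s voxels, dof = %d, contrast '%s' | t range [%.3g, %.3g] in mask (%d voxels)\n",
    paste(dim(x$t), collapse = "x"), x$dof, x$contrast,
    if (any(ok)) min(x$t[ok]) else NA, if (any(ok)) max(x$t[ok]) else NA,
    sum(x$analysis_mask)))
  invisible(x)
}

#' Threshold a statistical map and extract clusters
#'
#' Suprathreshold voxels have voxel-level `p < p_voxel` and a t sign
#' matching the map's contrast (the "combined voxel level" convention: an
#' uncorrected voxel p cutoff plus a cluster extent filter). Clusters are
#' 26-connected components; those smaller than `min_cluster_size` voxels are
#' removed. The cluster table is sorted by extent, descending.
#'
#' @param stat a `stat_map`.
#' @param p_voxel voxel-level p threshold (default 0.001).
#' @param min_cluster_size minimum cluster extent in voxels (default 10).
#' @param rois optional named list of binary ROI arrays; each cluster row
#'   then reports the overlap fraction with each ROI.
#' @return List with `mask` (binary array of surviving voxels) and `table`
#'   (data frame: `cluster_id`, `voxel_count`, `peak_t`, `peak_x/y/z`, and
#'   one `frac_<roi>` column per ROI).
#' @export
threshold_map <- function(stat, p_voxel = 0.001, min_cluster_size = 10L,
                          rois = NULL) {
  stopifnot(inherits(stat, "stat_map"))
  supra <- is.finite(stat$p) & stat$p < p_voxel
  if (stat$contrast %in% c("post<pre", "A<B")) supra <- supra & stat$t < 0
  if (stat$contrast %in% c("post>pre", "A>B")) supra <- supra & stat$t > 0
  d <- dim(stat$t)
  empty <- list(mask = array(0, d),
                table = cluster_table_skeleton(rois))
  if (!any(supra)) return(empty)
  lab <- label_components_26(as.logical(supra), as.integer(d))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_cluster_size)
  if (!length(keep)) return(empty)
  keep <- keep[order(sizes[keep], decreasing = TRUE)]
  mask <- array(0, d)
  rows <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    vox <- which(lab == keep[i])
    mask[vox] <- 1
    tv <- stat$t[vox]
    pk <- vox[which.max(abs(tv))]
    coord <- arrayInd(pk, d)
    row <- data.frame(cluster_id = i, voxel_count = length(vox),
                      peak_t = tv[which.max(abs(tv))],
                      peak_x = coord[1], peak_y = coord[2], peak_z = coord[3])
    if (!is.null(rois)) {
      for (nm in names(rois)) {
        r <- rois[[nm]]
        if (is_volume_grid(r)) r <- r$data
        row[[paste0("frac_", nm)]] <- mean(r[vox] > 0)
      }
    }
    rows[[i]] <- row
  }
  list(mask = mask, table = do.call(rbind, rows))
}

cluster_table_skeleton <- function(rois) {
  base <- data.frame(cluster_id = integer(0), voxel_count = integer(0),
                     peak_t = numeric(0), peak_x = integer(0),
                     peak_y = integer(0), peak_z = integer(0))
  if (!is.null(rois))
    for (nm in names(rois)) base[[paste0("frac_", nm)]] <- numeric(0)
  base
}

#' Dice overlap of two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`. Two empty masks give 1 (perfect
#' agreement on "nothing"); exactly one empty mask gives 0.
#'
#' @param mask_a,mask_b binary arrays (or [volume_grid()]s) of equal shape.
#' @return A value in `[0, 1]`.
#' @export
dice_overlap <- function(mask_a, mask_b) {
  if (is_volume_grid(mask_a)) mask_a <- mask_a$data
  if (is_volume_grid(mask_b)) mask_b <- mask_b$data
  if (!all(dim(mask_a) == dim(mask_b))) stop("mask shapes differ")
  a <- mask_a > 0; b <- mask_b > 0
  na <- sum(a); nb <- sum(b)
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  2 * sum(a & b) / (na + nb)
}

#' Write a stat map and its thresholded mask to disk
#'
#' Writes the t-map and binary mask as NIfTI, the cluster table as TSV, and
#' a JSON sidecar recording the contrast and thresholds.
#'
#' @param stat a `stat_map`.
#' @param thresholded the [threshold_map()] result for it.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @param voxel_size_mm voxel size for the NIfTI headers.
#' @param p_voxel,min_cluster_size thresholds to record in the sidecar.
#' @return `dir`, invisibly.
#' @export
write_stat_map <- function(stat, thresholded, dir, prefix = "statmap",
                           voxel_size_mm = 1.5, p_voxel = 0.001,
                           min_cluster_size = 10L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tmap <- stat$t
  tmap[!is.finite(tmap)] <- 0
  write_volume(volume_grid(tmap, voxel_size_mm),
               file.path(dir, paste0(prefix, "_tmap.nii.gz")))
  write_volume(volume_grid(thresholded$mask, voxel_size_mm),
               file.path(dir, paste0(prefix, "_mask.nii.gz")))
  utils::write.table(thresholded$table,
                     file.path(dir, paste0(prefix, "_clusters.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(contrast = stat$contrast, dof = stat$dof,
                            p_voxel = p_voxel,
                            min_cluster_size = min_cluster_size),
                       file.path(dir, paste0(prefix, "_sidecar.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
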