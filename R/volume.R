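#' 3D scalar volume with voxel geometry
#'
#' `volume_grid` is the image currency of the package: a 3D array of
#' gray-matter density values together with its isotropic voxel size (mm) and
#' a 4x4 voxel-to-world affine. All operators in the package consume and
#' produce this class.
#'
#' @param data 3D numeric array, all values finite.
#' @param voxel_size_mm positive scalar voxel edge length in millimetres.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   affine built from `voxel_size_mm`.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(data, voxel_size_mm = 1.5, affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array, got dimensionality ",
         length(dim(data)))
  if (!all(is.finite(data))) stop("`data` contains non-finite values")
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      voxel_size_mm <= 0)
    stop("`voxel_size_mm` must be a positive scalar")
  if (is.null(affine)) affine <- diag(c(rep(voxel_size_mm, 3L), 1))
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  structure(list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
                 affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_grid> %d x %d x %d voxels @ %.3g mm | range [%.4g, %.4g]\n",
              d[1], d[2], d[3], x$voxel_size_mm, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$data)

is_volume_grid <- function(x) inherits(x, "volume_grid")

stopifnot_same_grid <- function(a, b) {
  if (!all(dim(a$data) == dim(b$data)))
    stop("volume grid shapes differ: ", paste(dim(a$data), collapse = "x"),
         " vs ", paste(dim(b$data), collapse = "x"))
  invisible(TRUE)
}

#' Read a NIfTI-1 volume
#'
#' Reads a `.nii` or `.nii.gz` file into a [volume_grid()]. Only 3D images are
#' accepted; the voxel size is taken from the header `pixdim` and the affine
#' from the sform/qform.
#'
#' @param path path to a NIfTI-1 file.
#' @return A [volume_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nii <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  arr <- as.array(nii)
  arr <- array(as.numeric(arr), dim = dim(arr))  # drop RNifti attributes
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("'", path, "' is not a 3D volume (dimensionality ",
         length(dim(arr)), ")")
  px <- RNifti::pixdim(nii)[1:3]
  aff <- unclass(RNifti::xform(nii))
  attributes(aff) <- list(dim = c(4L, 4L))
  volume_grid(arr, voxel_size_mm = px[1], affine = aff)
}

#' Write a NIfTI-1 volume
#'
#' @param volume a [volume_grid()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(is_volume_grid(volume))
  nii <- RNifti::asNifti(volume$data)
  RNifti::pixdim(nii) <- rep(volume$voxel_size_mm, 3L)
  RNifti::sform(nii) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library calls do not perturb user randomness.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
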