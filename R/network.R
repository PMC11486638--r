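#' Generator architecture configuration
#'
#' The generator is a 3D U-Net: `n_encode_blocks` encoding blocks (two
#' kernel-3 convolutions with instance normalization and ReLU, then one
#' 2x max-pooling), a bottleneck of `n_resblocks` residual blocks, and a
#' mirror-symmetric decoder (one stride-2 transposed convolution for
#' upsampling, skip concatenation, then two convolutions). Channel width
#' doubles per level from `base_channels`. Convolutions followed by instance
#' normalization carry no bias (a per-channel constant is removed exactly by
#' the normalization).
#'
#' @param n_encode_blocks,n_decode_blocks encoder/decoder depth; must be
#'   equal (U-Net symmetry).
#' @param n_resblocks residual blocks in the bottleneck.
#' @param base_channels channels of the first level (small, e.g. 8-16, for
#'   desk-scale volumes).
#' @param final_activation `"tanh"` (default, for data mapped to `[-1, 1]`)
#'   or `"linear"`.
#' @return A `generator_config`.
#' @export
generator_config <- function(n_encode_blocks = 3L, n_decode_blocks = 3L,
                             n_resblocks = 6L, base_channels = 8L,
                             final_activation = c("tanh", "linear")) {
  final_activation <- match.arg(final_activation)
  if (n_encode_blocks != n_decode_blocks)
    stop("U-Net symmetry requires n_encode_blocks == n_decode_blocks")
  if (n_encode_blocks < 1L || n_resblocks < 0L || base_channels < 1L)
    stop("invalid generator configuration")
  structure(list(n_encode_blocks = as.integer(n_encode_blocks),
                 n_decode_blocks = as.integer(n_decode_blocks),
                 n_resblocks = as.integer(n_resblocks),
                 base_channels = as.integer(base_channels),
                 norm = "instance", activation = "relu",
                 skip_connections = TRUE,
                 final_activation = final_activation),
            class = "generator_config")
}

#' Discriminator architecture configuration
#'
#' A patch-level convolutional discriminator: `n_blocks` stride-2 kernel-3
#' convolutions with instance normalization and leaky ReLU, then a stride-1
#' convolution to a single-channel score map passed through a sigmoid, so
#' scores live in (0, 1). Each stride-2 block halves the grid, so the input
#' extent divided by `2^n_blocks` must be at least 2 (e.g. 5 blocks need
#' >= 64 voxels per axis; 32-voxel grids admit at most 4 blocks).
#'
#' @param n_blocks number of stride-2 blocks (default 4, the desk-scale
#'   setting for 32-voxel grids; 5 mirrors the full-scale architecture).
#' @param base_channels first-block channels; doubles per block, capped at
#'   8x.
#' @param leaky_slope negative-side slope of the leaky ReLU.
#' @return A `discriminator_config`.
#' @export
discriminator_config <- function(n_blocks = 4L, base_channels = 8L,
                                 leaky_slope = 0.2) {
  if (n_blocks < 1L || base_channels < 1L)
    stop("invalid discriminator configuration")
  structure(list(n_blocks = as.integer(n_blocks),
                 base_channels = as.integer(base_channels),
                 norm = "instance", activation = "leaky_relu",
                 leaky_slope = leaky_slope, output = "patch_sigmoid"),
            class = "discriminator_config")
}

check_generator_shape <- function(cfg, input_shape) {
  f <- 2^cfg$n_encode_blocks
  if (any(input_shape %% f != 0))
    stop("input shape (", paste(input_shape, collapse = "x"),
         ") must be divisible by 2^n_encode_blocks = ", f)
  invisible(TRUE)
}

check_discriminator_shape <- function(cfg, input_shape) {
  f <- 2^cfg$n_blocks
  if (any(input_shape %/% f < 2L) || any(input_shape %% f != 0))
    stop("input shape (", paste(input_shape, collapse = "x"),
         ") is too small for ", cfg$n_blocks,
         " stride-2 blocks: each axis must be a multiple of ", f,
         " with at least ", 2L * f,
         " voxels; reduce n_blocks (e.g. 4 blocks for 32-voxel grids)")
  invisible(TRUE)
}

# Build the C++ model holding both generators and both discriminators, with
# seeded He-initialized weights drawn from R's RNG.
build_cg_ptr <- function(gen_cfg, disc_cfg, input_shape, seed = NULL,
                         params = NULL) {
  check_generator_shape(gen_cfg, input_shape)
  check_discriminator_shape(disc_cfg, input_shape)
  ptr <- cg_build(list(n_levels = gen_cfg$n_encode_blocks,
                       n_resblocks = gen_cfg$n_resblocks,
                       base_channels = gen_cfg$base_channels,
                       tanh_out = identical(gen_cfg$final_activation, "tanh")),
                  list(n_blocks = disc_cfg$n_blocks,
                       base_channels = disc_cfg$base_channels),
                  as.integer(input_shape))
  if (is.null(params)) {
    info <- cg_param_info(ptr)
    params <- if (is.null(seed)) he_init_params(info)
              else with_seed(seed, he_init_params(info))
  }
  cg_set_params(ptr, params)
  ptr
}

he_init_params <- function(info) {
  lapply(info, function(net) {
    unlist(lapply(net, function(p) {
      w <- stats::rnorm(p$w_rows * p$w_cols, 0, sqrt(2 / p$fan_in))
      if (p$has_b) c(w, rep(0, p$b_len)) else w
    }), use.names = FALSE)
  })
}

#' Build a standalone generator network
#'
#' Constructs a seeded, initialized volume-to-volume network. Mostly useful
#' for architecture inspection and testing; training couples two generators
#' and two discriminators through [cyclegan()].
#'
#' @param cfg a [generator_config()].
#' @param input_shape integer vector of 3 extents, each divisible by
#'   `2^n_encode_blocks`.
#' @param seed seed for weight initialization.
#' @return An object of class `volume_net`; call [network_forward()] on it.
#' @export
build_generator <- function(cfg, input_shape, seed = 1L) {
  stopifnot(inherits(cfg, "generator_config"))
  input_shape <- as.integer(input_shape)
  # a minimal companion discriminator so the shared container can be built
  db <- discriminator_config(n_blocks = max(1L, min(
    2L, as.integer(log2(min(input_shape))) - 1L)), base_channels = 1L)
  ptr <- build_cg_ptr(cfg, db, input_shape, seed = seed)
  structure(list(kind = "generator", which = "g1", cfg = cfg,
                 input_shape = input_shape, ptr = ptr,
                 n_params = cg_param_counts(ptr)[["g1"]]),
            class = "volume_net")
}

#' Build a standalone discriminator network
#'
#' @param cfg a [discriminator_config()].
#' @param input_shape integer vector of 3 extents.
#' @param seed seed for weight initialization.
#' @return An object of class `volume_net` producing a patch score map in
#'   (0, 1).
#' @export
build_discriminator <- function(cfg, input_shape, seed = 1L) {
  stopifnot(inherits(cfg, "discriminator_config"))
  input_shape <- as.integer(input_shape)
  gen <- generator_config(n_encode_blocks = 1L, n_decode_blocks = 1L,
                          n_resblocks = 0L, base_channels = 1L)
  ptr <- build_cg_ptr(gen, cfg, input_shape, seed = seed)
  structure(list(kind = "discriminator", which = "da", cfg = cfg,
                 input_shape = input_shape, ptr = ptr,
                 n_params = cg_param_counts(ptr)[["da"]]),
            class = "volume_net")
}

#' Run a built network forward
#'
#' @param net a `volume_net` from [build_generator()] or
#'   [build_discriminator()].
#' @param x a [volume_grid()] or 3D array matching the build shape.
#' @return For a generator, a 3D array of the input shape; for a
#'   discriminator, a 3D score-map array (input shape divided by
#'   `2^n_blocks`).
#' @export
network_forward <- function(net, x) {
  stopifnot(inherits(net, "volume_net"))
  a <- if (is_volume_grid(x)) x$data else x
  if (!all(dim(a) == net$input_shape))
    stop("input shape ", paste(dim(a), collapse = "x"),
         " does not match build shape ",
         paste(net$input_shape, collapse = "x"))
  out <- cg_forward(net$ptr, net$which, as.numeric(a))
  d_out <- if (net$kind == "generator") net$input_shape
           else net$input_shape %/% 2^net$cfg$n_blocks
  array(out, dim = d_out)
}

#' @export
print.volume_net <- function(x, ...) {
  cat(sprintf("<volume_net> %s, input %s, %d parameters\n", x$kind,
              paste(x$input_shape, collapse = "x"), x$n_params))
  invisible(x)
}
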