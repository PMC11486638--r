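#' Fit a cycle-consistent adversarial translation model on two cohorts
#'
#' Trains two U-Net generators (`G1`: A to B, `G2`: B to A) and two patch
#' discriminators with alternating updates of the adversarial log-loss and
#' the L1 cycle-consistency loss. The total generator objective is the sum
#' of both adversarial terms plus `lambda_cycle` times the cycle loss.
#' Volumes are affinely mapped to `[-1, 1]` using a `data_max` computed from
#' the training volumes, and every forward pass through the fitted model
#' inverts that mapping and clips at zero.
#'
#' Training is fully reproducible given `seed` on a fixed platform: weight
#' initialization and epoch shuffling draw from an isolated R RNG stream and
#' the C++ training path is deterministic.
#'
#' @param domain_a,domain_b training data for the two domains: a `cohort`,
#'   or a list of [volume_grid()]s, or a list of 3D arrays. All volumes must
#'   share one grid shape.
#' @param gen_config a [generator_config()].
#' @param disc_config a [discriminator_config()].
#' @param lambda_cycle weight of the cycle-consistency loss (default 10; the
#'   adversarial weight is fixed at 1).
#' @param epochs passes over the training pairs (>= 1).
#' @param learning_rate,betas Adam settings (defaults 2e-4, c(0.5, 0.999)).
#' @param batch_size only 1 is supported (volumes are processed singly, the
#'   common choice for cycle-consistent translation).
#' @param seed integer controlling initialization and shuffling.
#' @param saturating if `TRUE`, the generator minimizes the literal
#'   `E[log(1 - D(G(x)))]` term; the default `FALSE` uses the standard
#'   non-saturating variant (maximize `E[log D(G(x))]`), which has the same
#'   fixed points but usable early gradients.
#' @param data_max scale of the `[-1, 1]` intensity mapping; default is the
#'   maximum voxel value over both training domains.
#' @param checkpoint_interval if not `NULL`, write the model to
#'   `checkpoint_dir` every that many epochs.
#' @param checkpoint_dir directory for checkpoints.
#' @param verbose print per-epoch losses.
#' @return An object of class `cyclegan` with the trained weights, both
#'   configurations, the `[-1, 1]` mapping scale, and a per-epoch
#'   `loss_history` data frame. Use [predict.cyclegan()] or
#'   [transform_volume()] to translate volumes.
#' @seealso [transform_volume()], [iterate_transform()],
#'   [save_cyclegan()]
#' @export
cyclegan <- function(domain_a, domain_b, gen_config = generator_config(),
                     disc_config = discriminator_config(),
                     lambda_cycle = 10, epochs = 40, learning_rate = 2e-4,
                     betas = c(0.5, 0.999), batch_size = 1L, seed = 1L,
                     saturating = FALSE, data_max = NULL,
                     checkpoint_interval = NULL, checkpoint_dir = NULL,
                     verbose = FALSE) {
  stopifnot(inherits(gen_config, "generator_config"),
            inherits(disc_config, "discriminator_config"))
  if (epochs < 1L) stop("`epochs` must be at least 1")
  if (!identical(as.integer(batch_size), 1L))
    stop("only batch_size = 1 is supported")
  if (lambda_cycle < 0) stop("`lambda_cycle` must be nonnegative")
  a_list <- domain_arrays(domain_a)
  b_list <- domain_arrays(domain_b)
  if (!length(a_list) || !length(b_list)) stop("empty training cohort")
  shape <- dim(a_list[[1]])
  for (v in c(a_list, b_list))
    if (!all(dim(v) == shape)) stop("training volumes differ in grid shape")
  check_disjoint_subjects(domain_a, domain_b)
  vox <- domain_voxel_size(domain_a)

  if (is.null(data_max))
    data_max <- max(vapply(c(a_list, b_list), max, numeric(1)))
  if (data_max <= 0) stop("`data_max` must be positive")
  a_net <- lapply(a_list, function(v) as.numeric(2 * v / data_max - 1))
  b_net <- lapply(b_list, function(v) as.numeric(2 * v / data_max - 1))

  ptr <- build_cg_ptr(gen_config, disc_config, shape, seed = seed)
  nA <- length(a_net); nB <- length(b_net)
  steps <- max(nA, nB)
  hist <- matrix(NA_real_, epochs, 5L,
                 dimnames = list(NULL,
                                 c("adv_a", "adv_b", "cyc", "gen_obj",
                                   "disc_obj")))
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ia <- rep_len(sample.int(nA), steps)
      ib <- rep_len(sample.int(nB), steps)
      acc <- numeric(5L)
      for (s in seq_len(steps)) {
        l <- cg_train_step(ptr, a_net[[ia[s]]], b_net[[ib[s]]], lambda_cycle,
                           learning_rate, betas[1], betas[2], !saturating)
        acc <- acc + l
      }
      hist[ep, ] <- acc / steps
      if (!all(is.finite(hist[ep, ])))
        stop("non-finite loss at epoch ", ep,
             "; training diverged (try a lower learning_rate)")
      if (verbose)
        message(sprintf(
          "epoch %3d | adv_a %8.4f adv_b %8.4f cyc %8.5f", ep,
          hist[ep, "adv_a"], hist[ep, "adv_b"], hist[ep, "cyc"]))
      if (!is.null(checkpoint_interval) && ep %% checkpoint_interval == 0L) {
        dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
        m <- cyclegan_state(ptr, gen_config, disc_config, shape, data_max,
                            hist[seq_len(ep), , drop = FALSE], seed, vox,
                            list(epochs = epochs, completed = ep,
                                 learning_rate = learning_rate,
                                 betas = betas, lambda_cycle = lambda_cycle,
                                 saturating = saturating))
        save_cyclegan(m, file.path(checkpoint_dir,
                                   sprintf("checkpoint_ep%03d.rds", ep)))
      }
    }
  })
  cyclegan_state(ptr, gen_config, disc_config, shape, data_max,
                 as.data.frame(hist), seed, vox,
                 list(epochs = epochs, completed = epochs,
                      learning_rate = learning_rate, betas = betas,
                      lambda_cycle = lambda_cycle, saturating = saturating))
}

cyclegan_state <- function(ptr, gen_config, disc_config, shape, data_max,
                           hist, seed, voxel_size_mm, train_config) {
  env <- new.env(parent = emptyenv())
  env$ptr <- ptr
  structure(list(gen_config = gen_config, disc_config = disc_config,
                 input_shape = as.integer(shape), data_max = data_max,
                 weights = cg_get_params(ptr),
                 loss_history = as.data.frame(hist), seed = seed,
                 voxel_size_mm = voxel_size_mm, train_config = train_config,
                 identity = FALSE, ptr_env = env),
            class = "cyclegan")
}

domain_arrays <- function(x) {
  if (inherits(x, "cohort")) x <- cohort_volumes(x)
  if (is_volume_grid(x)) x <- list(x)
  if (!is.list(x)) stop("domain input must be a cohort or a list of volumes")
  lapply(x, function(v) if (is_volume_grid(v)) v$data else v)
}

domain_voxel_size <- function(x) {
  if (inherits(x, "cohort")) return(x$spec$voxel_size_mm)
  if (is.list(x) && length(x) && is_volume_grid(x[[1]]))
    return(x[[1]]$voxel_size_mm)
  1.5
}

check_disjoint_subjects <- function(a, b) {
  if (inherits(a, "cohort") && inherits(b, "cohort")) {
    ia <- vapply(a$subjects, function(s) s$subject_id, character(1))
    ib <- vapply(b$subjects, function(s) s$subject_id, character(1))
    if (length(intersect(ia, ib)))
      stop("training cohorts share subject ids: ",
           paste(utils::head(intersect(ia, ib), 3L), collapse = ", "))
  }
  invisible(TRUE)
}

# Rebuild (or fetch the cached) C++ model behind a fitted object.
model_ptr <- function(model) {
  stopifnot(inherits(model, "cyclegan"))
  if (is.null(model$ptr_env))
    model$ptr_env <- new.env(parent = emptyenv())
  env <- model$ptr_env
  if (is.null(env$ptr) || !cg_ptr_ok(env$ptr)) {
    env$ptr <- build_cg_ptr(model$gen_config, model$disc_config,
                            model$input_shape, params = model$weights)
  }
  env$ptr
}

#' Translate a volume with a fitted model
#'
#' Applies the requested generator. The volume is mapped to the network
#' range with the model's training `data_max`, passed through the network,
#' mapped back, and clipped at zero (densities are nonnegative).
#'
#' @param model a fitted [cyclegan()] (or [identity_model()]).
#' @param volume a [volume_grid()] or 3D array matching the training shape.
#' @param direction `"a2b"` (G1) or `"b2a"` (G2).
#' @return A [volume_grid()] with the same geometry as the input.
#' @export
transform_volume <- function(model, volume, direction = c("a2b", "b2a")) {
  direction <- match.arg(direction)
  stopifnot(inherits(model, "cyclegan"))
  vg <- if (is_volume_grid(volume)) volume
        else volume_grid(volume, model$voxel_size_mm)
  if (!all(dim(vg$data) == model$input_shape))
    stop("volume shape ", paste(dim(vg$data), collapse = "x"),
         " does not match the model's training shape ",
         paste(model$input_shape, collapse = "x"))
  if (isTRUE(model$identity)) return(vg)
  x <- 2 * as.numeric(vg$data) / model$data_max - 1
  out <- cg_forward(model_ptr(model), if (direction == "a2b") "g1" else "g2",
                    x)
  out <- (out + 1) / 2 * model$data_max
  vg$data <- array(pmax(out, 0), dim = model$input_shape)
  vg
}

#' Iterate a translation n times
#'
#' Applies [transform_volume()] repeatedly; the k-th element of the result is
#' the volume transformed k times, emulating progressive change. Each output
#' carries a `provenance` attribute `"iteration-k"`.
#'
#' @inheritParams transform_volume
#' @param n_iterations number of repetitions (>= 1).
#' @return List of `n_iterations` [volume_grid()]s.
#' @export
iterate_transform <- function(model, volume, direction = c("a2b", "b2a"),
                              n_iterations = 5L) {
  direction <- match.arg(direction)
  n_iterations <- as.integer(n_iterations)
  if (n_iterations < 1L) stop("`n_iterations` must be at least 1")
  out <- vector("list", n_iterations)
  cur <- volume
  for (k in seq_len(n_iterations)) {
    cur <- transform_volume(model, cur, direction)
    attr(cur, "provenance") <- paste0("iteration-", k)
    out[[k]] <- cur
  }
  out
}

#' @export
#' @rdname transform_volume
#' @param object,newdata standard [predict()] arguments; `newdata` may be a
#'   single volume, a list of volumes, or a `cohort` (a list of translated
#'   volumes is returned for the latter two).
#' @param iterations apply the generator this many times (see
#'   [iterate_transform()]); the final iterate is returned.
#' @param ... unused.
predict.cyclegan <- function(object, newdata,
                             direction = c("a2b", "b2a"), iterations = 1L,
                             ...) {
  direction <- match.arg(direction)
  one <- function(v) {
    if (iterations == 1L) transform_volume(object, v, direction)
    else iterate_transform(object, v, direction, iterations)[[iterations]]
  }
  if (inherits(newdata, "cohort")) return(lapply(cohort_volumes(newdata), one))
  if (is_volume_grid(newdata) ||
      (is.array(newdata) && length(dim(newdata)) == 3L)) return(one(newdata))
  if (is.list(newdata)) return(lapply(newdata, one))
  stop("`newdata` must be a volume, a list of volumes, or a cohort")
}

#' Identity translation model
#'
#' A `cyclegan`-classed model whose transform is the exact identity map.
#' Useful as a fixed-point control in progression and null experiments
#' (instance normalization makes an exact parameter-level identity
#' unrepresentable in the network itself).
#'
#' @param input_shape integer vector of 3 extents.
#' @param voxel_size_mm voxel size of the volumes it will be applied to.
#' @return An object of class `cyclegan` with `identity = TRUE`.
#' @export
identity_model <- function(input_shape, voxel_size_mm = 1.5) {
  structure(list(gen_config = NULL, disc_config = NULL,
                 input_shape = as.integer(input_shape), data_max = 1,
                 weights = NULL, loss_history = NULL, seed = NA_integer_,
                 voxel_size_mm = voxel_size_mm, train_config = NULL,
                 identity = TRUE, ptr_env = new.env(parent = emptyenv())),
            class = "cyclegan")
}

#' Save / load a fitted model
#'
#' The checkpoint holds the weights (exact single-precision values), both
#' architecture configurations, the intensity-mapping scale, the seed, and
#' the loss history; save, load, and transform is bit-identical to
#' transforming before saving.
#'
#' @param model a fitted [cyclegan()].
#' @param path checkpoint file path (`.rds`).
#' @return `save_cyclegan`: `path`, invisibly; `load_cyclegan`: the model.
#' @export
save_cyclegan <- function(model, path) {
  stopifnot(inherits(model, "cyclegan"))
  slim <- model
  slim$ptr_env <- NULL
  saveRDS(slim, path)
  invisible(path)
}

#' @rdname save_cyclegan
#' @export
load_cyclegan <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cyclegan")) stop("'", path,
                                         "' is not a cyclegan checkpoint")
  model$ptr_env <- new.env(parent = emptyenv())
  model
}

#' @export
print.cyclegan <- function(x, ...) {
  if (isTRUE(x$identity)) {
    cat("<cyclegan> identity model on ",
        paste(x$input_shape, collapse = "x"), " volumes\n", sep = "")
    return(invisible(x))
  }
  cat("<cyclegan> 3D unpaired translation model\n")
  cat("  input: ", paste(x$input_shape, collapse = "x"), " voxels @ ",
      x$voxel_size_mm, " mm\n", sep = "")
  cat("  generator: U-Net, ", x$gen_config$n_encode_blocks, " levels, ",
      x$gen_config$n_resblocks, " resblocks, base ",
      x$gen_config$base_channels, " channels\n", sep = "")
  cat("  discriminator: ", x$disc_config$n_blocks, " stride-2 blocks\n",
      sep = "")
  n <- nrow(x$loss_history)
  cat(sprintf("  trained %d epochs | final adv (A, B) = (%.3f, %.3f), cycle = %.4f\n",
              n, x$loss_history$adv_a[n], x$loss_history$adv_b[n],
              x$loss_history$cyc[n]))
  invisible(x)
}

#' @export
summary.cyclegan <- function(object, ...) {
  counts <- if (isTRUE(object$identity)) NULL
            else vapply(object$weights, length, integer(1))
  out <- list(input_shape = object$input_shape,
              n_params = counts,
              data_max = object$data_max,
              train_config = object$train_config,
              loss_history = object$loss_history)
  class(out) <- "summary.cyclegan"
  out
}

#' @export
print.summary.cyclegan <- function(x, ...) {
  cat("CycleGAN volume translation model\n")
  cat("  input shape:", paste(x$input_shape, collapse = "x"), "\n")
  if (!is.null(x$n_params)) {
    cat("  parameters: ",
        paste(sprintf("%s=%d", names(x$n_params), x$n_params),
              collapse = ", "), "\n")
    cat("  data_max:", format(x$data_max), "\n")
    cat("  lambda_cycle:", x$train_config$lambda_cycle,
        "| lr:", x$train_config$learning_rate,
        "| epochs:", x$train_config$completed, "\n")
    cat("  loss history (last 5 epochs):\n")
    print(utils::tail(round(x$loss_history, 4), 5))
  }
  invisible(x)
}

#' @export
#' @importFrom graphics matplot legend
plot.cyclegan <- function(x, ...) {
  if (isTRUE(x$identity) || is.null(x$loss_history))
    stop("no loss history to plot")
  h <- x$loss_history
  graphics::matplot(seq_len(nrow(h)), cbind(h$cyc, -h$adv_a, -h$adv_b),
                    type = "l", lty = 1, col = c("black", "steelblue",
                                                 "firebrick"),
                    xlab = "epoch", ylab = "loss",
                    main = "CycleGAN training losses", ...)
  graphics::legend("topright", c("cycle (L1)", "-adv A", "-adv B"),
                   col = c("black", "steelblue", "firebrick"), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Stratified k-fold split of a two-group cohort
#'
#' Partitions each group separately into k folds whose sizes differ by at
#' most one, so every validation fold mixes both groups (e.g. 71 + 71
#' subjects at k = 10 give per-group validation folds of 7 or 8). Which
#' folds receive the remainder subjects is randomized.
#'
#' @param groups a `cohort`, or a vector of group labels (one per subject).
#' @param k number of folds (>= 2; at most the smaller group size).
#' @param seed integer seed for the shuffles.
#' @return A list of k elements, each `list(train = idx, validation = idx)`
#'   of integer subject indices; validation folds partition the cohort.
#' @export
stratified_kfold_split <- function(groups, k, seed = 1L) {
  if (inherits(groups, "cohort")) groups <- cohort_groups(groups)
  groups <- as.character(groups)
  k <- as.integer(k)
  if (k < 2L) stop("`k` must be at least 2 (k = 1 leaves no validation set)")
  tab <- table(groups)
  if (any(tab < k))
    stop("`k` = ", k, " exceeds the size of group '",
         names(tab)[which.min(tab)], "' (", min(tab), ")")
  n <- length(groups)
  fold_of <- integer(n)
  with_seed(seed, {
    for (g in names(tab)) {
      idx <- sample(which(groups == g))
      base <- length(idx) %/% k
      extra <- length(idx) %% k
      sizes <- rep(base, k)
      if (extra > 0) sizes[sample.int(k, extra)] <- base + 1L
      fold_of[idx] <- rep(seq_len(k), times = sizes)
    }
  })
  lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), validation = which(fold_of == f)))
}
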