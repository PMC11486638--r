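# shared tiny training fixture: 4 + 4 subjects on an 8^3 grid, cached once
tiny_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- phantom_spec(grid_shape = c(8, 8, 8), n_structures = 2L,
                          structure_smoothness_mm = 3, seed = 5L)
      coh <- generate_cohort(spec, 4, effect = NULL, seed = 6)
      m <- cyclegan(cohort_volumes(coh, "HS"), cohort_volumes(coh, "SZ"),
                    gen_config = generator_config(2, 2, 1, 2),
                    disc_config = discriminator_config(2, 2),
                    epochs = 2, seed = 9)
      cache <<- list(spec = spec, coh = coh, model = m)
    }
    cache
  }
})

test_that("training bookkeeping: loss history, reproducibility, validation", {
  fx <- tiny_fit()
  m <- fx$model
  expect_s3_class(m, "cyclegan")
  expect_equal(nrow(m$loss_history), 2L)
  expect_true(all(is.finite(as.matrix(m$loss_history))))

  # identical seed reproduces the final losses and weights exactly
  m2 <- cyclegan(cohort_volumes(fx$coh, "HS"), cohort_volumes(fx$coh, "SZ"),
                 gen_config = generator_config(2, 2, 1, 2),
                 disc_config = discriminator_config(2, 2),
                 epochs = 2, seed = 9)
  expect_identical(m$loss_history, m2$loss_history)
  expect_identical(m$weights, m2$weights)

  # another seed gives a different model
  m3 <- cyclegan(cohort_volumes(fx$coh, "HS"), cohort_volumes(fx$coh, "SZ"),
                 gen_config = generator_config(2, 2, 1, 2),
                 disc_config = discriminator_config(2, 2),
                 epochs = 2, seed = 10)
  expect_false(identical(m$weights$g1, m3$weights$g1))

  expect_error(cyclegan(list(), list()), "empty")
  expect_error(cyclegan(cohort_volumes(fx$coh, "HS"),
                        cohort_volumes(fx$coh, "SZ"), batch_size = 2),
               "batch_size")
  expect_error(cyclegan(fx$coh, fx$coh), "share subject ids")
})

test_that("strong cycle weight drives reconstruction below the initial value", {
  fx <- tiny_fit()
  hs <- cohort_volumes(fx$coh, "HS"); sz <- cohort_volumes(fx$coh, "SZ")
  m <- cyclegan(hs, sz, gen_config = generator_config(2, 2, 1, 2),
                disc_config = discriminator_config(2, 2),
                lambda_cycle = 1e3, epochs = 6, seed = 4)
  h <- m$loss_history$cyc
  expect_lt(h[length(h)], h[1])
})

test_that("transform output is finite, nonnegative, and shape-checked", {
  fx <- tiny_fit()
  v <- cohort_volumes(fx$coh, "HS")[[1]]
  out <- transform_volume(fx$model, v, "a2b")
  expect_true(all(is.finite(out$data)))
  expect_true(all(out$data >= 0))
  expect_equal(dim(out$data), dim(v$data))
  expect_error(transform_volume(fx$model, random_volume(c(16, 16, 16))),
               "shape")
})

test_that("iteration composes the transform and labels provenance", {
  fx <- tiny_fit()
  v <- cohort_volumes(fx$coh, "HS")[[1]]
  it <- iterate_transform(fx$model, v, "a2b", 3)
  expect_length(it, 3L)
  expect_identical(attr(it[[2]], "provenance"), "iteration-2")
  # n = 1 equals a single transform; applying twice equals iterate n = 2
  one <- transform_volume(fx$model, v, "a2b")
  expect_identical(it[[1]]$data, one$data)
  two <- transform_volume(fx$model, one, "a2b")
  expect_identical(it[[2]]$data, two$data)
  expect_error(iterate_transform(fx$model, v, "a2b", 0), "at least 1")

  # the identity model is a fixed point of iteration
  id <- identity_model(dim(v$data), v$voxel_size_mm)
  it_id <- iterate_transform(id, v, "a2b", 4)
  for (k in 1:4) expect_identical(it_id[[k]]$data, v$data)
})

test_that("serialization round trip is bit-identical", {
  fx <- tiny_fit()
  v <- cohort_volumes(fx$coh, "HS")[[2]]
  before <- transform_volume(fx$model, v, "a2b")
  path <- tempfile(fileext = ".rds")
  save_cyclegan(fx$model, path)
  loaded <- load_cyclegan(path)
  after <- transform_volume(loaded, v, "a2b")
  expect_identical(before$data, after$data)
  expect_identical(loaded$weights, fx$model$weights)
  # wrong payloads are rejected
  saveRDS(list(1), path)
  expect_error(load_cyclegan(path), "not a cyclegan")
})

test_that("stratified folds partition each group into near-equal parts", {
  groups <- rep(c("HS", "SZ"), each = 71)
  folds <- stratified_kfold_split(groups, 10, seed = 2)
  expect_length(folds, 10L)
  val_sizes_hs <- vapply(folds, function(f)
    sum(groups[f$validation] == "HS"), integer(1))
  val_sizes_sz <- vapply(folds, function(f)
    sum(groups[f$validation] == "SZ"), integer(1))
  # 71 = 7 x 9 + 8: per-group fold sizes are 7 or 8
  expect_true(all(val_sizes_hs %in% c(7L, 8L)))
  expect_true(all(val_sizes_sz %in% c(7L, 8L)))
  expect_equal(sum(val_sizes_hs), 71L)
  # perfect partition: every subject in exactly one validation fold
  all_val <- sort(unlist(lapply(folds, `[[`, "validation")))
  expect_identical(all_val, 1:142)
  for (f in folds) {
    expect_length(intersect(f$train, f$validation), 0L)
    expect_identical(sort(c(f$train, f$validation)), 1:142)
  }
  expect_error(stratified_kfold_split(groups, 1), "at least 2")
  expect_error(stratified_kfold_split(rep(c("a", "b"), c(5, 100)), 10),
               "exceeds")
})

test_that("same-seed fold assignments are stable, different seeds differ", {
  groups <- rep(c("a", "b"), each = 20)
  f1 <- stratified_kfold_split(groups, 5, seed = 3)
  f2 <- stratified_kfold_split(groups, 5, seed = 3)
  expect_identical(f1, f2)
  f3 <- stratified_kfold_split(groups, 5, seed = 4)
  expect_false(identical(f1, f3))
})
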