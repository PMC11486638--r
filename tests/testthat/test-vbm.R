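test_that("paired t-map matches the scalar-loop oracle and hand values", {
  set.seed(21)
  n <- 10
  pre <- lapply(1:n, function(i) random_volume(c(8, 8, 8), seed = 100 + i))
  post <- lapply(1:n, function(i) random_volume(c(8, 8, 8), seed = 200 + i))
  tm <- paired_t_map(pre, post)
  oracle <- paired_t_oracle(pre, post)
  expect_lt(max(abs(tm$t - oracle$t), na.rm = TRUE), 1e-10)
  expect_lt(max(abs(tm$p - oracle$p), na.rm = TRUE), 1e-10)
  expect_equal(tm$dof, n - 1L)

  # single-voxel hand check: diffs (1, 2, 3) -> t = 3.4641, dof = 2
  mk <- function(vals) lapply(vals, function(v)
    volume_grid(array(v, c(2, 2, 2))))
  tm1 <- paired_t_map(mk(c(0, 0, 0)), mk(c(1, 2, 3)))
  expect_equal(round(tm1$t[1, 1, 1], 4), 3.4641)
  expect_equal(tm1$dof, 2L)

  # post == pre: zero variance everywhere -> NaN, nothing suprathreshold
  tm0 <- paired_t_map(pre, pre)
  expect_true(all(is.nan(tm0$t)))
  th0 <- threshold_map(tm0, 0.001, 1)
  expect_equal(sum(th0$mask), 0)
})

test_that("paired t-map is antisymmetric in its arguments", {
  pre <- lapply(1:6, function(i) random_volume(c(6, 6, 6), seed = 300 + i))
  post <- lapply(1:6, function(i) random_volume(c(6, 6, 6), seed = 400 + i))
  a <- paired_t_map(pre, post)
  b <- paired_t_map(post, pre)
  expect_equal(a$t, -b$t, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("two-sample t-map matches the oracle and detects a separation", {
  ga <- lapply(1:5, function(i) random_volume(c(6, 6, 6), seed = 500 + i))
  gb <- lapply(1:7, function(i) random_volume(c(6, 6, 6), seed = 600 + i))
  tm <- two_sample_t_map(ga, gb)
  expect_lt(max(abs(tm$t - two_sample_t_oracle(ga, gb)), na.rm = TRUE),
            1e-10)
  expect_equal(tm$dof, 10L)

  # identical groups give t = 0 where variance > 0
  tid <- two_sample_t_map(ga, ga)
  expect_true(all(abs(tid$t[is.finite(tid$t)]) < 1e-12))

  # constructed separation: A near 0, B near 1 -> large negative t (A < B)
  set.seed(7)
  mk <- function(mu) lapply(1:4, function(i)
    volume_grid(array(mu + rnorm(8, 0, 1e-3), c(2, 2, 2))))
  ts <- two_sample_t_map(mk(0), mk(1))
  expect_true(all(ts$t < -100))
})

test_that("t-maps are invariant to common global scaling of all inputs", {
  pre <- lapply(1:8, function(i) random_volume(c(6, 6, 6), seed = 700 + i))
  post <- lapply(1:8, function(i) {
    v <- random_volume(c(6, 6, 6), seed = 800 + i)
    v$data <- v$data + 0.3
    v
  })
  t1 <- paired_t_map(lapply(pre, global_scale, target_mean = 50),
                     lapply(post, global_scale, target_mean = 50))
  t2 <- paired_t_map(lapply(pre, global_scale, target_mean = 7),
                     lapply(post, global_scale, target_mean = 7))
  expect_equal(t1$t, t2$t, tolerance = 1e-8)
})

test_that("threshold_map extracts 26-connected clusters above the size cut", {
  d <- c(12, 12, 12)
  tvals <- array(0, d)
  tvals[2:6, 3:4, 5] <- 10          # 10-voxel block
  n <- 40
  p <- 2 * pt(-abs(tvals), n - 1)
  stat <- structure(list(t = tvals, p = array(p, d), dof = n - 1,
                         contrast = "post>pre",
                         analysis_mask = array(TRUE, d), n = n),
                    class = "stat_map")
  th <- threshold_map(stat, 0.001, min_cluster_size = 5)
  expect_equal(nrow(th$table), 1L)
  expect_equal(th$table$voxel_count, 10L)
  expect_equal(th$table$peak_t, 10)
  # raising the extent cut removes it
  th2 <- threshold_map(stat, 0.001, min_cluster_size = 20)
  expect_equal(nrow(th2$table), 0L)
  expect_equal(sum(th2$mask), 0)
  # contrast sign gating: same map with "post<pre" keeps nothing
  stat$contrast <- "post<pre"
  expect_equal(sum(threshold_map(stat, 0.001, 5)$mask), 0)
  # diagonal voxels are one 26-connected cluster
  tvals2 <- array(0, d)
  tvals2[cbind(1:5, 1:5, 1:5)] <- 10
  stat2 <- structure(list(t = tvals2, p = 2 * pt(-abs(tvals2), n - 1),
                          dof = n - 1, contrast = "two-sided",
                          analysis_mask = array(TRUE, d), n = n),
                     class = "stat_map")
  th3 <- threshold_map(stat2, 0.001, 1)
  expect_equal(nrow(th3$table), 1L)
  expect_equal(th3$table$voxel_count, 5L)
})

test_that("dice overlap handles the empty-mask conventions", {
  d <- c(6, 6, 6)
  a <- array(0, d); b <- array(0, d)
  expect_equal(dice_overlap(a, b), 1)
  a[1:10] <- 1
  expect_equal(dice_overlap(a, b), 0)
  b[1:10] <- 1
  expect_equal(dice_overlap(a, b), 1)
  b[] <- 0; b[6:15] <- 1  # overlap 5, each 10
  expect_equal(dice_overlap(a, b), 0.5)
  expect_error(dice_overlap(a, array(0, c(5, 5, 5))), "differ")
})

test_that("suprathreshold rate is calibrated under the null", {
  # independent-noise phantoms, no effect: p < 0.001 rate within 3 binomial
  # SE of 0.001 (pooled over replicates)
  # pure iid-normal voxel null: no jitter, no age trend, unsmoothed noise
  spec <- tiny_spec(subject_jitter_sd = 0, noise_sd = 0.05,
                    atrophy_per_year = 0)
  tpl <- make_template(spec)
  support <- tpl$data > 0.05
  hits <- 0; total <- 0
  for (r in 1:8) {
    coh <- generate_cohort(spec, 8, effect = NULL, seed = 900 + r)
    tm <- two_sample_t_map(cohort_volumes(coh, "HS"),
                           cohort_volumes(coh, "SZ"), mask = support)
    hits <- hits + sum(tm$p < 0.001, na.rm = TRUE)
    total <- total + sum(is.finite(tm$p))
  }
  rate <- hits / total
  se <- sqrt(0.001 * 0.999 / total)
  expect_lt(abs(rate - 0.001), 3 * se)
})
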