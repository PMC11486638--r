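test_that("configuration invariants are enforced", {
  expect_error(generator_config(n_encode_blocks = 3, n_decode_blocks = 2),
               "symmetry")
  expect_s3_class(generator_config(), "generator_config")
  expect_error(discriminator_config(0), "invalid")
  # a 32-voxel grid cannot feed 5 stride-2 blocks (32 / 2^5 = 1)
  expect_error(build_discriminator(discriminator_config(n_blocks = 5),
                                   c(32, 32, 32)),
               "reduce n_blocks")
  # generator needs divisibility by 2^levels
  expect_error(build_generator(generator_config(), c(30, 32, 32)),
               "divisible")
})

test_that("generator preserves shape, discriminator downsamples into (0,1)", {
  g <- build_generator(generator_config(2, 2, 1, 2), c(16, 16, 16), seed = 1)
  x <- random_volume(c(16, 16, 16), seed = 2)
  out <- network_forward(g, x)
  expect_equal(dim(out), c(16L, 16L, 16L))
  expect_true(all(is.finite(out)))
  # forward is deterministic with fixed parameters
  expect_identical(out, network_forward(g, x))

  d <- build_discriminator(discriminator_config(3, 2), c(16, 16, 16),
                           seed = 1)
  s <- network_forward(d, x)
  expect_equal(dim(s), c(2L, 2L, 2L))
  expect_true(all(s > 0 & s < 1))
})

test_that("parameter counts match the architecture arithmetic", {
  # frozen regression values, cross-checked against a hand count:
  # L=2, R=1, base=2 generator and B=2, base=2 discriminator
  g <- build_generator(generator_config(2, 2, 1, 2), c(8, 8, 8))
  d <- build_discriminator(discriminator_config(2, 2), c(8, 8, 8))
  hand_conv <- function(ci, co) 27 * ci * co
  hand_tconv <- function(ci, co) 8 * ci * co
  gen_expected <-
    hand_conv(1, 2) + hand_conv(2, 2) +      # enc level 0
    hand_conv(2, 4) + hand_conv(4, 4) +      # enc level 1
    2 * hand_conv(4, 4) +                    # 1 resblock
    hand_tconv(4, 4) + hand_conv(8, 2) + hand_conv(2, 2) +  # dec level 1
    hand_tconv(2, 2) + hand_conv(4, 2) + hand_conv(2, 2) +  # dec level 0
    hand_conv(2, 1) + 1                      # final conv + bias
  expect_equal(g$n_params, gen_expected)
  disc_expected <- hand_conv(1, 2) + hand_conv(2, 4) + hand_conv(4, 1) + 1
  expect_equal(d$n_params, disc_expected)
})

test_that("analytic gradients match finite differences", {
  gcfg <- generator_config(2, 2, 1, 2)
  dcfg <- discriminator_config(2, 2)
  shape <- c(8L, 8L, 8L)
  ptr <- cyclemorph:::build_cg_ptr(gcfg, dcfg, shape, seed = 7)
  set.seed(42)
  x <- as.numeric(array(tanh(rnorm(512, 0, 0.6)), shape))
  y <- as.numeric(array(tanh(rnorm(512, 0, 0.6)), shape))
  p0 <- cyclemorph:::cg_get_params(ptr)

  # generator objective: directional derivative along the analytic gradient
  gg <- cyclemorph:::cg_gen_grads(ptr, x, y, 10, TRUE)
  gnorm2 <- sum(gg$g1^2) + sum(gg$g2^2)
  h <- 1e-5
  pp <- p0; pp$g1 <- p0$g1 + h * gg$g1; pp$g2 <- p0$g2 + h * gg$g2
  cyclemorph:::cg_set_params(ptr, pp)
  lp <- cyclemorph:::cg_gen_grads(ptr, x, y, 10, TRUE)$loss
  pm <- p0; pm$g1 <- p0$g1 - h * gg$g1; pm$g2 <- p0$g2 - h * gg$g2
  cyclemorph:::cg_set_params(ptr, pm)
  lm_ <- cyclemorph:::cg_gen_grads(ptr, x, y, 10, TRUE)$loss
  num <- (lp - lm_) / (2 * h)
  expect_lt(abs(num - gnorm2) / gnorm2, 0.05)
  cyclemorph:::cg_set_params(ptr, p0)

  # discriminator objective: per-coordinate finite differences
  dd <- cyclemorph:::cg_disc_grads(ptr, x, y)
  set.seed(1)
  idx <- sample(length(p0$da), 25)
  h2 <- 5e-3
  rel <- vapply(idx, function(i) {
    pp <- p0; pp$da[i] <- pp$da[i] + h2
    cyclemorph:::cg_set_params(ptr, pp)
    lp <- cyclemorph:::cg_disc_grads(ptr, x, y)$loss
    pp$da[i] <- pp$da[i] - 2 * h2
    cyclemorph:::cg_set_params(ptr, pp)
    lm2 <- cyclemorph:::cg_disc_grads(ptr, x, y)$loss
    num <- (lp - lm2) / (2 * h2)
    abs(num - dd$da[i]) / max(1e-6, abs(num) + abs(dd$da[i]))
  }, numeric(1))
  cyclemorph:::cg_set_params(ptr, p0)
  expect_lt(median(rel), 0.01)
})

test_that("batch independence: discriminator treats volumes separately", {
  d <- build_discriminator(discriminator_config(2, 2), c(8, 8, 8), seed = 3)
  a <- random_volume(c(8, 8, 8), seed = 1)
  b <- random_volume(c(8, 8, 8), seed = 2)
  sa <- network_forward(d, a)
  sb <- network_forward(d, b)
  # processing in the other order changes nothing (no cross-batch state)
  sb2 <- network_forward(d, b)
  sa2 <- network_forward(d, a)
  expect_identical(sa, sa2)
  expect_identical(sb, sb2)
})
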