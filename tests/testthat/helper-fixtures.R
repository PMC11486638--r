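# Shared fixtures: tiny phantom specs and cached expensive objects.

tiny_spec <- function(seed = 11L, ...) {
  phantom_spec(grid_shape = c(16L, 16L, 16L), n_structures = 4L,
               structure_smoothness_mm = 3, seed = seed, ...)
}

# a small deterministic random volume
random_volume <- function(shape = c(8L, 8L, 8L), seed = 1L,
                          voxel_size_mm = 1.5) {
  set.seed(seed)
  volume_grid(array(abs(rnorm(prod(shape))), dim = shape), voxel_size_mm)
}

# scalar-loop paired t oracle: returns list(t, p) arrays
paired_t_oracle <- function(pre, post) {
  d <- dim(pre[[1]]$data)
  n <- length(pre)
  tv <- array(NA_real_, d); pv <- array(NA_real_, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    diffs <- vapply(seq_len(n),
                    function(s) post[[s]]$data[i, j, k] - pre[[s]]$data[i, j, k],
                    numeric(1))
    s <- sd(diffs)
    if (s > 0) {
      tv[i, j, k] <- mean(diffs) / (s / sqrt(n))
      pv[i, j, k] <- 2 * pt(-abs(tv[i, j, k]), n - 1)
    } else {
      tv[i, j, k] <- NaN; pv[i, j, k] <- NaN
    }
  }
  list(t = tv, p = pv)
}

two_sample_t_oracle <- function(ga, gb) {
  d <- dim(ga[[1]]$data)
  na <- length(ga); nb <- length(gb)
  tv <- array(NA_real_, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    a <- vapply(ga, function(v) v$data[i, j, k], numeric(1))
    b <- vapply(gb, function(v) v$data[i, j, k], numeric(1))
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    tv[i, j, k] <- if (se > 0) (mean(a) - mean(b)) / se else NaN
  }
  tv
}
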