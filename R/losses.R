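#' Adversarial (log) loss of a discriminator on real and fake scores
#'
#' Value of the adversarial objective
#' `E[log D(y)] + E[log(1 - D(G(x)))]`
#' for one translation direction, averaged over all score-map entries. The
#' discriminator maximizes this quantity; the generator minimizes the second
#' term (or, in the non-saturating variant used for training updates,
#' maximizes `E[log D(G(x))]`). Scores outside `(0, 1)` are clamped to
#' `[1e-7, 1 - 1e-7]` and the clamping is reported via a message.
#'
#' @param disc_scores_real numeric vector/array of discriminator scores on
#'   real volumes.
#' @param disc_scores_fake numeric scores on generated volumes.
#' @return Scalar loss value (nonpositive; supremum 0 as D(real) -> 1 and
#'   D(fake) -> 0).
#' @export
adversarial_loss <- function(disc_scores_real, disc_scores_fake) {
  r <- as.numeric(disc_scores_real)
  f <- as.numeric(disc_scores_fake)
  if (!length(r) || !length(f)) stop("empty score input")
  eps <- 1e-7
  n_out <- sum(r <= 0 | r >= 1) + sum(f <= 0 | f >= 1)
  if (n_out > 0)
    message("adversarial_loss: clamped ", n_out,
            " score(s) outside (0, 1) to [", eps, ", 1 - ", eps, "]")
  r <- pmin(pmax(r, eps), 1 - eps)
  f <- pmin(pmax(f, eps), 1 - eps)
  mean(log(r)) + mean(log(1 - f))
}

#' Cycle-consistency loss
#'
#' Mean absolute (L1) reconstruction error in both translation directions,
#' summed: `E||G2(G1(x)) - x|| + E||G1(G2(y)) - y||`.
#'
#' @param x,x_reconstructed volumes (or arrays) of domain A and their
#'   two-generator reconstructions.
#' @param y,y_reconstructed same for domain B.
#' @return Scalar loss (0 on perfect reconstruction).
#' @export
cycle_loss <- function(x, x_reconstructed, y, y_reconstructed) {
  xs <- as_loss_array(x); xr <- as_loss_array(x_reconstructed)
  ys <- as_loss_array(y); yr <- as_loss_array(y_reconstructed)
  if (length(xs) != length(xr) || length(ys) != length(yr))
    stop("shape mismatch between inputs and reconstructions")
  mean(abs(xr - xs)) + mean(abs(yr - ys))
}

as_loss_array <- function(v) {
  if (is_volume_grid(v)) return(as.numeric(v$data))
  if (is.list(v)) return(unlist(lapply(v, as_loss_array), use.names = FALSE))
  as.numeric(v)
}
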