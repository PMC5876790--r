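# Blind source separation of the RGB channels.
#
# The observed channels x are modelled as an instantaneous linear mixture of
# statistically independent sources s; the unmixing transform W with s = W x
# is estimated by maximizing non-Gaussianity of the projections (a negentropy
# proxy), the classical fixed-point scheme with deflation. Outputs are
# defined only up to permutation and sign, which downstream selection must
# (and does) tolerate.

E_LOGCOSH_GAUSS <- 0.3745672  # E[log cosh Z], Z ~ N(0,1); negentropy reference

#' Unmix an RGB trace into independent source signals
#'
#' Whitens the (preprocessed) channel matrix and runs a deflation fixed-point
#' iteration with the `tanh` (log-cosh) contrast to extract three maximally
#' independent components. Deterministic given `seed`, which fixes the random
#' initial directions.
#'
#' @param trace an [rgb_trace()], normally the output of
#'   [preprocess_trace()].
#' @param seed integer seed for the initial unmixing directions.
#' @param max_iter maximum fixed-point iterations per component.
#' @param tol convergence tolerance on the direction update
#'   (`|<w, w_old>| > 1 - tol`).
#' @param min_samples minimum number of frames required; defaults to
#'   `10 * sampling_rate` (ten seconds of signal).
#' @return A list of class `ica_fit` with components
#'   \describe{
#'     \item{sources}{n x 3 matrix of zero-mean source signals, in
#'       extraction order.}
#'     \item{W}{3 x 3 unmixing matrix: `sources = t(W %*% t(centered
#'       channels))`.}
#'     \item{component_order}{integer permutation recording output order.}
#'     \item{independence_score}{summed squared negentropy proxy of the
#'       sources.}
#'     \item{converged}{logical per component.}
#'   }
#' @export
ica_unmix <- function(trace, seed = 1L, max_iter = 200L, tol = 1e-6,
                      min_samples = NULL) {
  stopifnot(inherits(trace, "rgb_trace"))
  X <- trace_matrix(trace)  # n x 3
  n <- nrow(X)
  if (is.null(min_samples)) min_samples <- ceiling(10 * trace$sampling_rate)
  if (n < max(min_samples, 4L)) {
    stop(sprintf("ica_unmix: need at least %d samples, got %d",
                 max(min_samples, 4L), n), call. = FALSE)
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc, nu = 0, nv = 0)$d
  if (sv[3L] < 1e-8 * sv[1L]) {
    stop(structure(
      class = c("cribwatch_degenerate_input", "error", "condition"),
      list(message = "ica_unmix: rank-deficient input (channels are linearly dependent)",
           call = sys.call(-1))))
  }
  # whitening: Z has identity covariance
  cv <- crossprod(Xc) / (n - 1)
  eg <- eigen(cv, symmetric = TRUE)
  K <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)  # 3 x 3
  Z <- Xc %*% t(K)                                  # n x 3, white

  Wrot <- matrix(0, 3L, 3L)
  converged <- logical(3L)
  init <- withr::with_seed(as.integer(seed), matrix(stats::rnorm(9L), 3L, 3L))
  for (p in 1:3) {
    w <- init[p, ]
    if (p > 1L) {
      prev <- Wrot[seq_len(p - 1L), , drop = FALSE]
      w <- w - drop(t(prev) %*% (prev %*% w))
    }
    w <- w / sqrt(sum(w^2))
    for (it in seq_len(max_iter)) {
      wx <- drop(Z %*% w)
      g <- tanh(wx)
      gp <- 1 - g^2
      w_new <- drop(crossprod(Z, g)) / n - mean(gp) * w
      if (p > 1L) {
        prev <- Wrot[seq_len(p - 1L), , drop = FALSE]
        w_new <- w_new - drop(t(prev) %*% (prev %*% w_new))
      }
      nrm <- sqrt(sum(w_new^2))
      if (nrm < 1e-12) break
      w_new <- w_new / nrm
      done <- abs(sum(w_new * w)) > 1 - tol
      w <- w_new
      if (done) { converged[p] <- TRUE; break }
    }
    Wrot[p, ] <- w
  }
  W <- Wrot %*% K           # unmixing for centered observations
  S <- Xc %*% t(W)          # n x 3 sources, unit variance by whitening
  # deterministic sign convention: largest-magnitude unmixing weight positive
  for (p in 1:3) {
    j <- which.max(abs(W[p, ]))
    if (W[p, j] < 0) { W[p, ] <- -W[p, ]; S[, p] <- -S[, p] }
  }
  neg <- colMeans(log(cosh(S))) - E_LOGCOSH_GAUSS
  structure(
    list(sources = S, W = W, component_order = 1:3,
         independence_score = sum(neg^2), converged = converged,
         sampling_rate = trace$sampling_rate),
    class = "ica_fit"
  )
}

#' @export
print.ica_fit <- function(x, ...) {
  cat(sprintf("<ica_fit> %d samples, 3 components, independence score %.4g\n",
              nrow(x$sources), x$independence_score))
  cat("converged:", paste(x$converged, collapse = " "), "\n")
  invisible(x)
}
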