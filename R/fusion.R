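# Iterative attentional feature fusion (iAFF) with multi-scale channel
# attention (MS-CAM), adapted from the image domain to tabular N x D
# feature matrices: the matrix is treated as a 1-channel map, lifted to C
# channels by a 1x1 projection, gated, fused, and collapsed back.

#' Fusion configuration
#'
#' @param channels number of lifted channels C (divisible by `ratio`).
#' @param ratio channel scaling ratio r, the bottleneck divisor; the
#'   MS-CAM bottleneck maps C -> C/r -> C.
#' @param seed parameter-initialization seed.
#' @return object of class `kgrdr_fusion_config`.
#' @export
fusion_config <- function(channels = 16, ratio = 4, seed = 1) {
  if (ratio < 1) stop_invalid("ratio must be >= 1")
  if (channels %% ratio != 0) {
    stop_invalid("channels (%d) must be divisible by ratio (%d)",
                 channels, ratio)
  }
  structure(list(channels = channels, ratio = ratio, seed = seed),
            class = "kgrdr_fusion_config")
}

#' Initialize fusion parameters
#'
#' The 1x1 channel lift is initialized near identity per channel
#' (`w_c ~ 1 + N(0, 0.01)`, zero bias) and the collapse projection is its
#' exact left inverse, so collapse(lift(F)) = F; the two MS-CAM bottlenecks
#' (global pooled context and local pointwise context) get `N(0, 0.01)`
#' weights and zero biases.
#'
#' @param config a [fusion_config()].
#' @return list of parameter arrays.
#' @export
fusion_params <- function(config) {
  C <- config$channels
  Cr <- C %/% config$ratio
  with_seed(config$seed, {
    p <- list(
      lift_w = 1 + stats::rnorm(C, sd = 0.1),
      lift_b = rep(0, C),
      g_W1 = matrix(stats::rnorm(Cr * C, sd = 0.1), Cr, C),
      g_b1 = rep(0, Cr),
      g_W2 = matrix(stats::rnorm(C * Cr, sd = 0.1), C, Cr),
      g_b2 = rep(0, C),
      l_W1 = matrix(stats::rnorm(Cr * C, sd = 0.1), Cr, C),
      l_b1 = rep(0, Cr),
      l_W2 = matrix(stats::rnorm(C * Cr, sd = 0.1), C, Cr),
      l_b2 = rep(0, C)
    )
    # collapse = left inverse of the lift
    p$collapse_w <- p$lift_w / sum(p$lift_w^2)
    p$collapse_b <- -sum(p$collapse_w * p$lift_b)
    p
  })
}

#' Lift a feature matrix to a C-channel map
#'
#' 1x1 convolutional projection from one channel to C channels:
#' channel c of the output is `lift_w[c] * F + lift_b[c]`.
#'
#' @param F numeric N x D matrix.
#' @param params parameters from [fusion_params()].
#' @return array of shape (C, N, D).
#' @export
channel_lift <- function(F, params) {
  C <- length(params$lift_w)
  out <- array(0, dim = c(C, nrow(F), ncol(F)))
  for (c in seq_len(C)) {
    out[c, , ] <- params$lift_w[c] * F + params$lift_b[c]
  }
  out
}

channel_collapse <- function(map, params) {
  C <- dim(map)[1]
  out <- matrix(params$collapse_b, dim(map)[2], dim(map)[3])
  for (c in seq_len(C)) out <- out + params$collapse_w[c] * map[c, , ]
  out
}

#' Multi-scale channel attention gate
#'
#' `gate = sigmoid(global_context + local_context)`: the global branch
#' applies a C -> C/r -> C bottleneck (ReLU between) to the per-channel
#' global average pool and broadcasts it; the local branch applies its own
#' bottleneck pointwise at every (n, d) position.  All entries lie strictly
#' in (0, 1).
#'
#' @param F_lifted array (C, N, D) from [channel_lift()].
#' @param params parameters from [fusion_params()].
#' @return gate array of shape (C, N, D) with entries in (0, 1).
#' @export
ms_cam <- function(F_lifted, params) {
  d <- dim(F_lifted)
  C <- d[1]; N <- d[2]; D <- d[3]
  if (ncol(params$g_W1) != C) {
    stop_invalid("parameter shapes do not match the %d-channel map", C)
  }
  Fm <- matrix(F_lifted, C, N * D)        # channels x positions
  gap <- rowMeans(Fm)
  gvec <- drop(params$g_W2 %*% relu(params$g_W1 %*% gap + params$g_b1)) +
    params$g_b2
  loc <- params$l_W2 %*% relu(params$l_W1 %*% Fm + params$l_b1) + params$l_b2
  gate <- sigmoid(loc + gvec)             # gvec recycles down columns
  array(gate, dim = c(C, N, D))
}

#' Attentional feature fusion of two feature matrices
#'
#' Computes the MS-CAM gate on the lifted sum `X + Y` and returns the gated
#' convex combination `M (x) X + (1 - M) (x) Y`, collapsed back to N x D.
#'
#' @param X,Y numeric N x D matrices.
#' @param params parameters from [fusion_params()].
#' @param details if `TRUE`, return a list with the fused matrix and gate.
#' @return fused N x D matrix (or detail list).
#' @export
aff <- function(X, Y, params, details = FALSE) {
  if (!all(dim(X) == dim(Y))) stop_invalid("X and Y must have the same shape")
  gate <- ms_cam(channel_lift(X + Y, params), params)
  fused_map <- gate * channel_lift(X, params) +
    (1 - gate) * channel_lift(Y, params)
  fused <- channel_collapse(fused_map, params)
  dimnames(fused) <- dimnames(X)
  if (details) list(fused = fused, gate = gate) else fused
}

#' Iterative attentional feature fusion (two-stage)
#'
#' The first-stage fusion [aff()] produces an intermediate map whose MS-CAM
#' gate then reweights the *original* inputs:
#' `Z = M(aff(X, Y)) (x) X + (1 - M(aff(X, Y))) (x) Y`.
#'
#' @inheritParams aff
#' @return fused N x D matrix `Z` (or detail list with both stage gates).
#' @export
iaff <- function(X, Y, params, details = FALSE) {
  stage1 <- aff(X, Y, params, details = TRUE)
  gate2 <- ms_cam(channel_lift(stage1$fused, params), params)
  Z_map <- gate2 * channel_lift(X, params) +
    (1 - gate2) * channel_lift(Y, params)
  Z <- channel_collapse(Z_map, params)
  dimnames(Z) <- dimnames(X)
  if (details) {
    list(fused = Z, gate1 = stage1$gate, gate2 = gate2,
         stage1 = stage1$fused)
  } else {
    Z
  }
}
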