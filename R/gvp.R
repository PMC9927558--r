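## Geometric vector perceptron (vector-gated form) with hand-derived
## gradients, plus the equivariance-preserving LayerNorm and Dropout used by
## the propagation and feed-forward updates.
##
## Vector channels are stored axis-major: a (3n) x nv matrix whose rows
## 1..n are x components, n+1..2n are y, 2n+1..3n are z. All vector-channel
## operations act per channel-column and therefore commute with any rotation
## applied across the three axis blocks, which is what makes the layer
## equivariant: scalars only ever see vector *norms*.

## squared norms per (row, channel): (3n) x nv -> n x nv
v_norms2 <- function(V, n) {
  V2 <- V * V
  V2[seq_len(n), , drop = FALSE] +
    V2[n + seq_len(n), , drop = FALSE] +
    V2[2L * n + seq_len(n), , drop = FALSE]
}

## gather vector rows for node indices idx: (3n) x nv -> (3m) x nv
v_gather <- function(V, idx, n) {
  V[c(idx, n + idx, 2L * n + idx), , drop = FALSE]
}

## replicate an n x k matrix across the three axis blocks -> (3n) x k
v_rep3 <- function(M) rbind(M, M, M)

## apply a 3x3 linear map (rotation/reflection) to every vector
v_rotate <- function(V, R, n) {
  i1 <- seq_len(n); i2 <- n + i1; i3 <- 2L * n + i1
  X <- V[i1, , drop = FALSE]; Y <- V[i2, , drop = FALSE]
  Z <- V[i3, , drop = FALSE]
  rbind(R[1, 1] * X + R[1, 2] * Y + R[1, 3] * Z,
        R[2, 1] * X + R[2, 2] * Y + R[2, 3] * Z,
        R[3, 1] * X + R[3, 2] * Y + R[3, 3] * Z)
}

#' Initialize one GVP layer
#'
#' A GVP maps a (scalar, vector) tuple to a (scalar, vector) tuple. Vectors
#' are first mixed by `Wh` into `h = max(vi, vo)` hidden channels; their norms
#' join the scalar channel, which a dense map `Wm` transforms; output vectors
#' are a second mix `Wmu` of the hidden vectors, gated per channel by a
#' sigmoid of a linear map (`Wg`) of the pre-activation scalars. Scalar
#' activation is ReLU when `activate` is TRUE (hidden layers) and identity
#' otherwise (final layer of a chain).
#'
#' @param si,vi input scalar / vector channel counts (vi may be 0).
#' @param so,vo output scalar / vector channel counts (vo may be 0; vo > 0
#'   requires vi > 0, since output vectors must be built equivariantly from
#'   input vectors).
#' @param activate apply ReLU to output scalars.
#' @return parameter list (class `gvp_params`).
#' @keywords internal
gvp_init <- function(si, vi, so, vo, activate = TRUE) {
  if (vo > 0L && vi == 0L)
    grank_stop("a GVP cannot emit vectors without vector inputs",
               "grank_config_error")
  h <- if (vi > 0L) max(vi, vo) else 0L
  ## the dense scalar map acts on the concatenation [s, rownorms(Wh V)]; it
  ## is stored as two blocks (Ws | Wn) so neither pass has to materialize
  ## the concatenated matrix
  p <- list(
    Ws = matrix(stats::rnorm(si * so, sd = sqrt(2 / (si + h))), nrow = so),
    bm = numeric(so)
  )
  if (vi > 0L) {
    p$Wn <- matrix(stats::rnorm(h * so, sd = sqrt(2 / (si + h))), nrow = so)
    p$Wh <- matrix(stats::rnorm(vi * h, sd = sqrt(1 / vi)), nrow = h)
  }
  if (vo > 0L) {
    p$Wmu <- matrix(stats::rnorm(h * vo, sd = sqrt(1 / h)), nrow = vo)
    p$Wg <- matrix(stats::rnorm(so * vo, sd = sqrt(1 / so)), nrow = vo)
    p$bg <- numeric(vo)
  }
  attr(p, "dims") <- c(si = si, vi = vi, so = so, vo = vo, h = h)
  attr(p, "activate") <- activate
  class(p) <- "gvp_params"
  p
}

#' Forward pass of one GVP layer
#'
#' @param s n x si scalar matrix.
#' @param V (3n) x vi axis-major vector matrix (or NULL when vi = 0).
#' @param p `gvp_params`.
#' @return list(s, V, cache); `cache` holds the intermediates the backward
#'   pass needs.
#' @keywords internal
gvp_forward <- function(s, V, p) {
  dm <- attr(p, "dims")
  n <- nrow(s)
  cache <- list(s = s, V = V, n = n)
  s_pre <- s %*% t(p$Ws)
  if (dm[["vi"]] > 0L) {
    Vh <- V %*% t(p$Wh)                       # (3n) x h
    nrm <- sqrt(v_norms2(Vh, n))              # n x h
    s_pre <- s_pre + nrm %*% t(p$Wn)
    cache$Vh <- Vh; cache$nrm <- nrm
  }
  s_pre <- s_pre + rep(p$bm, each = n)
  cache$s_pre <- s_pre
  s_out <- if (isTRUE(attr(p, "activate"))) relu(s_pre) else s_pre
  V_out <- NULL
  if (dm[["vo"]] > 0L) {
    Vmu <- cache$Vh %*% t(p$Wmu)              # (3n) x vo
    gate <- sigmoid(s_pre %*% t(p$Wg) + rep(p$bg, each = n))  # n x vo
    V_out <- Vmu * v_rep3(gate)
    cache$Vmu <- Vmu; cache$gate <- gate
  }
  list(s = s_out, V = V_out, cache = cache)
}

#' Backward pass of one GVP layer
#'
#' @param dS gradient w.r.t. output scalars (n x so).
#' @param dV gradient w.r.t. output vectors ((3n) x vo, or NULL).
#' @param p `gvp_params`; `cache` from [gvp_forward()].
#' @return list(ds, dV, grads) with input gradients and parameter gradients
#'   (same structure as `p`).
#' @keywords internal
gvp_backward <- function(dS, dV, p, cache) {
  dm <- attr(p, "dims")
  n <- cache$n
  g <- list()
  ds_pre <- if (isTRUE(attr(p, "activate"))) dS * (cache$s_pre > 0) else dS
  dVh <- NULL
  if (dm[["vo"]] > 0L && !is.null(dV)) {
    gate3 <- v_rep3(cache$gate)
    dVmu <- dV * gate3
    dgate <- v_norms_sum(dV * cache$Vmu, n)   # n x vo: sum over axis blocks
    dgp <- dgate * cache$gate * (1 - cache$gate)
    g$Wg <- crossprod(dgp, cache$s_pre)       # vo x so
    g$bg <- colSums(dgp)
    ds_pre <- ds_pre + dgp %*% p$Wg
    g$Wmu <- crossprod(dVmu, cache$Vh)        # vo x h
    dVh <- dVmu %*% p$Wmu
  }
  g$Ws <- crossprod(ds_pre, cache$s)
  g$bm <- colSums(ds_pre)
  ds <- ds_pre %*% p$Ws
  dV_in <- NULL
  if (dm[["vi"]] > 0L) {
    g$Wn <- crossprod(ds_pre, cache$nrm)
    dnrm <- ds_pre %*% p$Wn
    ## d|v| / dv = v / |v|; guard the gradient at exactly zero norm
    scale <- dnrm / pmax(cache$nrm, 1e-12)
    dVh2 <- cache$Vh * v_rep3(scale)
    dVh <- if (is.null(dVh)) dVh2 else dVh + dVh2
    g$Wh <- crossprod(dVh, cache$V)           # h x vi
    dV_in <- dVh %*% p$Wh
  }
  list(ds = ds, dV = dV_in, grads = g)
}

## sum an axis-major (3n) x k matrix over the three axis blocks -> n x k
v_norms_sum <- function(M, n) {
  M[seq_len(n), , drop = FALSE] +
    M[n + seq_len(n), , drop = FALSE] +
    M[2L * n + seq_len(n), , drop = FALSE]
}

## ---------------------------------------------------------------------------
## Tuple LayerNorm (no learned affine parameters):
##  - scalar channel: standard per-row normalization across features;
##  - vector channel: each node's vectors divided by the root-mean-square of
##    its channel norms (no centering, so rotating the input rotates the
##    output: equivariance is preserved).

LN_EPS <- 1e-6

ln_forward <- function(s, V, n) {
  mu <- rowMeans(s)
  xc <- s - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + LN_EPS)
  s_out <- xc * inv
  cache <- list(xc = xc, inv = inv, n = n)
  V_out <- NULL
  if (!is.null(V) && ncol(V) > 0L) {
    nv <- ncol(V)
    r2 <- rowMeans(v_norms2(V, n)) + LN_EPS   # n
    rinv <- 1 / sqrt(r2)
    V_out <- V * v_rep3(matrix(rinv, ncol = 1L))[, rep(1L, nv), drop = FALSE]
    cache$V <- V; cache$rinv <- rinv; cache$nv <- nv
  }
  list(s = s_out, V = V_out, cache = cache)
}

ln_backward <- function(dS, dV, cache) {
  k <- ncol(cache$xc)
  xhat <- cache$xc * cache$inv
  ## standard layer-norm backward (no affine): per row
  dsum <- rowSums(dS)
  dxh_x <- rowSums(dS * xhat)
  ds <- cache$inv * (dS - dsum / k - xhat * dxh_x / k)
  dV_in <- NULL
  if (!is.null(dV)) {
    n <- cache$n; nv <- cache$nv
    rinv <- cache$rinv
    dot <- rowSums(v_norms_sum(dV * cache$V, n))  # n: sum over channels+axes
    rinv3 <- v_rep3(matrix(rinv, ncol = 1L))[, rep(1L, nv), drop = FALSE]
    corr <- dot * rinv^3 / nv                     # n
    corr3 <- v_rep3(matrix(corr, ncol = 1L))[, rep(1L, nv), drop = FALSE]
    dV_in <- dV * rinv3 - cache$V * corr3
  }
  list(ds = ds, dV = dV_in)
}

## ---------------------------------------------------------------------------
## Dropout. Scalars: elementwise inverted dropout. Vectors: whole 3-vectors
## are dropped per (node, channel) so the direction of surviving vectors is
## untouched. Identity in eval mode.

drop_forward <- function(s, V, n, rate, training) {
  if (!training || rate <= 0) {
    return(list(s = s, V = V, cache = list(identity = TRUE)))
  }
  ms <- matrix(stats::rbinom(length(s), 1L, 1 - rate), nrow(s)) / (1 - rate)
  cache <- list(identity = FALSE, ms = ms)
  s_out <- s * ms
  V_out <- NULL
  if (!is.null(V) && ncol(V) > 0L) {
    mv <- matrix(stats::rbinom(n * ncol(V), 1L, 1 - rate), n) / (1 - rate)
    mv3 <- v_rep3(mv)
    V_out <- V * mv3
    cache$mv3 <- mv3
  }
  list(s = s_out, V = V_out, cache = cache)
}

drop_backward <- function(dS, dV, cache) {
  if (isTRUE(cache$identity)) return(list(ds = dS, dV = dV))
  list(ds = dS * cache$ms,
       dV = if (is.null(dV)) NULL else dV * cache$mv3)
}
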