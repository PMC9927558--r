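## The scoring network. Input GVPs lift node one-hots and RBF/unit-vector edge
## features into (scalar, vector) tuples; a GVPConv block — a graph
## propagation layer (messages from 3 chained GVPs, mean-aggregated over
## incoming edges, residual + LayerNorm) followed by a point-wise feed-forward
## layer (2 chained GVPs, residual + LayerNorm) — is repeated n_blocks times;
## a final GVP reduces every node to scalars, which are mean-pooled per graph
## and passed through a two-layer dense head to one score per graph.

#' Model configuration
#'
#' @param node_dims c(scalar, vector) hidden channel counts per node.
#' @param edge_dims c(scalar, vector) channel counts per edge.
#' @param n_blocks number of GVPConv blocks (5 reproduces the reference
#'   architecture; smaller values are supported for CPU-scale experiments).
#' @param n_message_gvps,n_ff_gvps GVPs in the propagation message function
#'   and the feed-forward update (3 and 2 in the reference architecture).
#' @param dropout_rate dropout probability during training.
#' @param n_rbf radial basis functions per edge (must match the graphs).
#' @param dense_hidden width of the hidden dense layer of the output head.
#' @param seed seed for parameter initialization.
#' @return a `grank_config` list.
#' @export
grank_config <- function(node_dims = c(100L, 16L), edge_dims = c(32L, 1L),
                         n_blocks = 5L, n_message_gvps = 3L, n_ff_gvps = 2L,
                         dropout_rate = 0.1, n_rbf = 16L, dense_hidden = 128L,
                         seed = 1L) {
  stopifnot(length(node_dims) == 2L, length(edge_dims) == 2L,
            all(node_dims >= 1L), all(edge_dims >= 1L), n_blocks >= 1L,
            n_message_gvps >= 1L, n_ff_gvps >= 1L,
            dropout_rate >= 0, dropout_rate < 1, n_rbf >= 2L,
            dense_hidden >= 1L)
  structure(list(
    node_dims = as.integer(node_dims), edge_dims = as.integer(edge_dims),
    n_blocks = as.integer(n_blocks),
    n_message_gvps = as.integer(n_message_gvps),
    n_ff_gvps = as.integer(n_ff_gvps),
    dropout_rate = dropout_rate, n_rbf = as.integer(n_rbf),
    dense_hidden = as.integer(dense_hidden), seed = as.integer(seed)
  ), class = "grank_config")
}

gvp_chain_init <- function(n_layers, si, vi, so, vo) {
  ## hidden tuples use the output dims; the last layer has no activation
  lapply(seq_len(n_layers), function(l) {
    gvp_init(if (l == 1L) si else so, if (l == 1L) vi else vo,
             so, vo, activate = l < n_layers)
  })
}

#' Initialize all network parameters
#'
#' All draws come from one generator seeded with `config$seed`, so the state
#' is reproducible.
#'
#' @param config a `grank_config`.
#' @return a `grank_state`: list(config, params).
#' @export
grank_init <- function(config) {
  ns <- config$node_dims[1L]; nv <- config$node_dims[2L]
  es <- config$edge_dims[1L]; ev <- config$edge_dims[2L]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  params <- list(
    ## node inputs: 5 one-hot scalars + one zero vector channel
    node_in = gvp_init(5L, 1L, ns, nv, activate = FALSE),
    edge_in = gvp_init(config$n_rbf, 1L, es, ev, activate = FALSE),
    blocks = lapply(seq_len(config$n_blocks), function(b) list(
      msg = gvp_chain_init(config$n_message_gvps, ns + es, nv + ev, ns, nv),
      ff  = gvp_chain_init(config$n_ff_gvps, ns, nv, ns, nv)
    )),
    out_gvp = gvp_init(ns, nv, ns, 0L, activate = TRUE),
    dense1 = list(W = matrix(stats::rnorm(ns * config$dense_hidden,
                                          sd = sqrt(2 / ns)),
                             nrow = config$dense_hidden),
                  b = numeric(config$dense_hidden)),
    ## regression-head conditioning: the final layer starts at zero, so the
    ## initial score is 0 for every graph and early optimizer steps go into
    ## shaping the readout rather than undoing a random output scale
    dense2 = list(W = matrix(0, nrow = 1L, ncol = config$dense_hidden),
                  b = numeric(1L))
  )
  structure(list(config = config, params = params), class = "grank_state")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

## ---------------------------------------------------------------------------
## Batching: several graphs are concatenated into one disconnected graph so a
## whole minibatch runs through the matrix ops in one pass. Per-graph scores
## are unaffected by batch composition because no edge crosses graphs and
## pooling is per graph.

#' Concatenate interface graphs into one batch
#'
#' @param graphs list of `interface_graph` objects (same `n_rbf`).
#' @return a `graph_batch` with node/edge features stacked, edge indices
#'   offset, and `graph_id` mapping nodes to graphs.
#' @export
build_batch <- function(graphs) {
  stopifnot(length(graphs) >= 1L)
  nn <- vapply(graphs, function(g) nrow(g$coords), integer(1L))
  offs <- cumsum(c(0L, nn[-length(nn)]))
  n <- sum(nn)
  edges <- do.call(rbind, Map(function(g, o) g$edges + o, graphs, offs))
  ne <- vapply(graphs, function(g) nrow(g$edges), integer(1L))
  ## edge vectors are axis-major per graph; re-interleave into batch layout
  ev <- lapply(graphs, function(g) matrix(g$edge_vector, ncol = 3L))
  edge_vector <- matrix(as.numeric(do.call(rbind, ev)), ncol = 1L)
  structure(list(
    n = n, n_graphs = length(graphs),
    graph_id = rep(seq_along(graphs), nn),
    node_scalar = do.call(rbind, lapply(graphs, `[[`, "node_scalar")),
    edges = edges,
    edge_scalar = do.call(rbind, lapply(graphs, `[[`, "edge_scalar")),
    edge_vector = edge_vector,
    complex_id = vapply(graphs, `[[`, "", "complex_id"),
    model_id = vapply(graphs, `[[`, "", "model_id")
  ), class = "graph_batch")
}

as_batch <- function(x) {
  if (inherits(x, "graph_batch")) x
  else if (inherits(x, "interface_graph")) build_batch(list(x))
  else build_batch(x)
}

## ---------------------------------------------------------------------------
## Forward

chain_forward <- function(s, V, chain) {
  caches <- vector("list", length(chain))
  for (l in seq_along(chain)) {
    out <- gvp_forward(s, V, chain[[l]])
    s <- out$s; V <- out$V; caches[[l]] <- out$cache
  }
  list(s = s, V = V, caches = caches)
}

chain_backward <- function(dS, dV, chain, caches) {
  grads <- vector("list", length(chain))
  for (l in rev(seq_along(chain))) {
    bk <- gvp_backward(dS, dV, chain[[l]], caches[[l]])
    dS <- bk$ds; dV <- bk$dV; grads[[l]] <- bk$grads
  }
  list(ds = dS, dV = dV, grads = grads)
}

## First GVP of the message chain, evaluated without materializing the
## concatenated per-edge inputs: the node-feature contributions are linear,
## so they are computed once per node and gathered per edge.
msg_gvp1_forward <- function(s, V, es, eV, src, n, p) {
  dm <- attr(p, "dims")
  ns <- ncol(s); nv <- ncol(V)
  Ws_node <- p$Ws[, seq_len(ns), drop = FALSE]
  Ws_edge <- p$Ws[, ns + seq_len(ncol(es)), drop = FALSE]
  Wh_node <- p$Wh[, seq_len(nv), drop = FALSE]
  Wh_edge <- p$Wh[, nv + seq_len(ncol(eV)), drop = FALSE]
  E <- length(src)
  s_pre <- (s %*% t(Ws_node))[src, , drop = FALSE] + es %*% t(Ws_edge)
  Vh <- v_gather(V %*% t(Wh_node), src, n) + eV %*% t(Wh_edge)
  nrm <- sqrt(v_norms2(Vh, E))
  s_pre <- s_pre + nrm %*% t(p$Wn) + rep(p$bm, each = E)
  s_out <- if (isTRUE(attr(p, "activate"))) relu(s_pre) else s_pre
  Vmu <- Vh %*% t(p$Wmu)
  gate <- sigmoid(s_pre %*% t(p$Wg) + rep(p$bg, each = E))
  cache <- list(s = s, V = V, es = es, eV = eV, n = E, Vh = Vh, nrm = nrm,
                s_pre = s_pre, gate = gate, Vmu = Vmu, ns = ns, nv = nv)
  list(s = s_out, V = Vmu * v_rep3(gate), cache = cache)
}

msg_gvp1_backward <- function(dS, dV, p, cache, src, n_nodes) {
  E <- cache$n
  g <- list()
  ds_pre <- if (isTRUE(attr(p, "activate"))) dS * (cache$s_pre > 0) else dS
  gate3 <- v_rep3(cache$gate)
  dVmu <- dV * gate3
  dgate <- v_norms_sum(dV * cache$Vmu, E)
  dgp <- dgate * cache$gate * (1 - cache$gate)
  g$Wg <- crossprod(dgp, cache$s_pre)
  g$bg <- colSums(dgp)
  ds_pre <- ds_pre + dgp %*% p$Wg
  g$Wmu <- crossprod(dVmu, cache$Vh)
  dVh <- dVmu %*% p$Wmu
  g$Wn <- crossprod(ds_pre, cache$nrm)
  dnrm <- ds_pre %*% p$Wn
  dVh <- dVh + cache$Vh * v_rep3(dnrm / pmax(cache$nrm, 1e-12))
  g$bm <- colSums(ds_pre)
  ns <- cache$ns; nv <- cache$nv
  Ws_node <- p$Ws[, seq_len(ns), drop = FALSE]
  Ws_edge <- p$Ws[, ns + seq_len(ncol(cache$es)), drop = FALSE]
  Wh_node <- p$Wh[, seq_len(nv), drop = FALSE]
  Wh_edge <- p$Wh[, nv + seq_len(ncol(cache$eV)), drop = FALSE]
  ## node contributions: aggregate per-edge gradients onto source nodes first
  ds_pre_nodes <- scatter_rows(ds_pre, src, n_nodes)
  dVh_nodes <- scatter_rows_v(dVh, src, n_nodes, E)
  g$Ws <- cbind(crossprod(ds_pre_nodes, cache$s), crossprod(ds_pre, cache$es))
  g$Wh <- cbind(crossprod(dVh_nodes, cache$V), crossprod(dVh, cache$eV))
  list(ds = ds_pre_nodes %*% Ws_node, dV = dVh_nodes %*% Wh_node,
       des = ds_pre %*% Ws_edge, deV = dVh %*% Wh_edge, grads = g)
}

## sum rows of an m x k matrix into n groups (zero rows for empty groups)
scatter_rows <- function(M, group, n) {
  out <- matrix(0, n, ncol(M))
  rs <- rowsum(M, group)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

## same for an axis-major (3m) x k matrix -> (3n) x k
scatter_rows_v <- function(M, group, n, m) {
  scatter_rows(M, c(group, n + group, 2L * n + group), 3L * n)
}

propagate_forward <- function(s, V, es, eV, edges, n, msg_chain,
                              rate, training) {
  src <- edges[, 1L]; dst <- edges[, 2L]
  E <- length(src)
  g1 <- msg_gvp1_forward(s, V, es, eV, src, n, msg_chain[[1L]])
  ch <- chain_forward(g1$s, g1$V, msg_chain[-1L])
  ch$caches <- c(list(g1$cache), ch$caches)
  ## mean over incoming edges; nodes with no incoming edge keep a zero message
  counts <- tabulate(dst, nbins = n)
  agg_s <- scatter_rows(ch$s, dst, n) / pmax(counts, 1L)
  nv <- ncol(ch$V)
  agg_V <- scatter_rows_v(ch$V, dst, n, E) /
    v_rep3(matrix(pmax(counts, 1L), ncol = 1L))[, rep(1L, nv), drop = FALSE]
  dr <- drop_forward(agg_s, agg_V, n, rate, training)
  ln <- ln_forward(s + dr$s, V + dr$V, n)
  list(s = ln$s, V = ln$V,
       cache = list(msg = ch$caches, drop = dr$cache, ln = ln$cache,
                    src = src, dst = dst, counts = counts, n = n, E = E,
                    nv = nv, n_msg_s = ncol(ch$s)))
}

propagate_backward <- function(dS, dV, msg_chain, cache) {
  n <- cache$n
  ln <- ln_backward(dS, dV, cache$ln)
  ## residual: gradient flows both into the node embedding and the message
  dr <- drop_backward(ln$ds, ln$dV, cache$drop)
  counts <- pmax(cache$counts, 1L)
  dmsg_s <- (dr$ds / counts)[cache$dst, , drop = FALSE]
  dV_scaled <- dr$dV / v_rep3(matrix(counts, ncol = 1L))[, rep(1L, cache$nv),
                                                         drop = FALSE]
  dmsg_V <- v_gather(dV_scaled, cache$dst, n)
  bk <- chain_backward(dmsg_s, dmsg_V, msg_chain[-1L], cache$msg[-1L])
  g1 <- msg_gvp1_backward(bk$ds, bk$dV, msg_chain[[1L]], cache$msg[[1L]],
                          cache$src, n)
  list(ds = ln$ds + g1$ds, dV = ln$dV + g1$dV, des = g1$des, deV = g1$deV,
       grads = c(list(g1$grads), bk$grads))
}

ff_forward <- function(s, V, ff_chain, rate, training, n) {
  ch <- chain_forward(s, V, ff_chain)
  dr <- drop_forward(ch$s, ch$V, n, rate, training)
  ln <- ln_forward(s + dr$s, V + dr$V, n)
  list(s = ln$s, V = ln$V,
       cache = list(ff = ch$caches, drop = dr$cache, ln = ln$cache))
}

ff_backward <- function(dS, dV, ff_chain, cache) {
  ln <- ln_backward(dS, dV, cache$ln)
  dr <- drop_backward(ln$ds, ln$dV, cache$drop)
  bk <- chain_backward(dr$ds, dr$dV, ff_chain, cache$ff)
  list(ds = ln$ds + bk$ds, dV = ln$dV + bk$dV, grads = bk$grads)
}

#' Full forward pass over a batch of graphs
#'
#' @param batch a `graph_batch` (or anything [build_batch()] accepts).
#' @param state a `grank_state`.
#' @param training logical; enables dropout (uses the current RNG stream).
#' @param keep_cache keep intermediates for [grank_backward()].
#' @return list(scores, cache): one score per graph.
#' @export
grank_forward <- function(batch, state, training = FALSE, keep_cache = FALSE) {
  batch <- as_batch(batch)
  p <- state$params
  cfg <- state$config
  n <- batch$n
  if (n == 0L) grank_stop("empty graph batch", "grank_empty_graph_error")
  if (ncol(batch$edge_scalar) != cfg$n_rbf)
    grank_stop("graph n_rbf does not match the model configuration",
               "grank_config_error")
  rate <- cfg$dropout_rate
  cache <- list(batch = batch)

  ni <- gvp_forward(batch$node_scalar, matrix(0, 3L * n, 1L), p$node_in)
  ei <- gvp_forward(batch$edge_scalar, batch$edge_vector, p$edge_in)
  s <- ni$s; V <- ni$V
  cache$node_in <- ni$cache; cache$edge_in <- ei$cache
  cache$blocks <- vector("list", cfg$n_blocks)
  for (b in seq_len(cfg$n_blocks)) {
    pr <- propagate_forward(s, V, ei$s, ei$V, batch$edges, n,
                            p$blocks[[b]]$msg, rate, training)
    ffo <- ff_forward(pr$s, pr$V, p$blocks[[b]]$ff, rate, training, n)
    s <- ffo$s; V <- ffo$V
    cache$blocks[[b]] <- list(prop = pr$cache, ff = ffo$cache)
  }
  og <- gvp_forward(s, V, p$out_gvp)          # scalars only
  ## mean pool per graph
  pooled <- rowsum(og$s, batch$graph_id) /
    as.numeric(tabulate(batch$graph_id, batch$n_graphs))
  h1_pre <- pooled %*% t(p$dense1$W) + rep(p$dense1$b, each = nrow(pooled))
  h1 <- relu(h1_pre)
  scores <- as.numeric(h1 %*% t(p$dense2$W) + p$dense2$b)
  if (keep_cache) {
    cache$out_gvp <- og$cache
    cache$pooled <- pooled; cache$h1_pre <- h1_pre; cache$h1 <- h1
    list(scores = scores, cache = cache)
  } else {
    list(scores = scores, cache = NULL)
  }
}

#' Backward pass: parameter gradients of a per-graph score loss
#'
#' @param dscores gradient of the loss w.r.t. each graph's score.
#' @param state the `grank_state` used in the forward pass.
#' @param cache cache from `grank_forward(..., keep_cache = TRUE)`.
#' @return parameter gradients, same structure as `state$params`.
#' @keywords internal
grank_backward <- function(dscores, state, cache) {
  p <- state$params
  batch <- cache$batch
  n <- batch$n
  g <- list()
  dh1 <- matrix(dscores, ncol = 1L) %*% p$dense2$W       # G x hidden
  g$dense2 <- list(W = crossprod(matrix(dscores, ncol = 1L), cache$h1),
                   b = sum(dscores))
  dh1_pre <- dh1 * (cache$h1_pre > 0)
  g$dense1 <- list(W = crossprod(dh1_pre, cache$pooled),
                   b = colSums(dh1_pre))
  dpooled <- dh1_pre %*% p$dense1$W                      # G x ns
  counts <- as.numeric(tabulate(batch$graph_id, batch$n_graphs))
  dnode_s <- (dpooled / counts)[batch$graph_id, , drop = FALSE]
  ob <- gvp_backward(dnode_s, NULL, p$out_gvp, cache$out_gvp)
  g$out_gvp <- ob$grads
  dS <- ob$ds; dV <- ob$dV
  cfg <- state$config
  g$blocks <- vector("list", cfg$n_blocks)
  des_total <- NULL; deV_total <- NULL
  for (b in rev(seq_len(cfg$n_blocks))) {
    fb <- ff_backward(dS, dV, p$blocks[[b]]$ff, cache$blocks[[b]]$ff)
    pb <- propagate_backward(fb$ds, fb$dV, p$blocks[[b]]$msg,
                             cache$blocks[[b]]$prop)
    dS <- pb$ds; dV <- pb$dV
    des_total <- if (is.null(des_total)) pb$des else des_total + pb$des
    deV_total <- if (is.null(deV_total)) pb$deV else deV_total + pb$deV
    g$blocks[[b]] <- list(msg = pb$grads, ff = fb$grads)
  }
  eb <- gvp_backward(des_total, deV_total, p$edge_in, cache$edge_in)
  g$edge_in <- eb$grads
  nb <- gvp_backward(dS, dV, p$node_in, cache$node_in)
  g$node_in <- nb$grads
  g
}

#' Score one interface graph
#'
#' Deterministic in eval mode; the score is invariant under any rotation,
#' translation or reflection of the input coordinates and under node
#' reordering.
#'
#' @param graph an `interface_graph`.
#' @param state a `grank_state`.
#' @param mode `"eval"` (deterministic, dropout off) or `"train"`.
#' @return a single numeric score.
#' @export
score_graph <- function(graph, state, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  grank_forward(graph, state, training = mode == "train")$scores[1L]
}

#' Ensemble score: mean over fold models
#'
#' @param states non-empty list of compatible `grank_state` objects.
#' @param graph an `interface_graph` or `graph_batch`.
#' @return numeric vector, one score per graph: the arithmetic mean of the
#'   member models' eval-mode scores.
#' @export
ensemble_predict <- function(states, graph) {
  if (!length(states)) grank_stop("empty ensemble", "grank_config_error")
  batch <- as_batch(graph)
  scores <- vapply(states, function(st) grank_forward(batch, st)$scores,
                   numeric(batch$n_graphs))
  if (batch$n_graphs == 1L) mean(scores) else rowMeans(matrix(
    scores, nrow = batch$n_graphs))
}

#' Save / load a model state
#'
#' Checkpoints are bit-exact: reloading reproduces eval-mode scores exactly.
#' @param state a `grank_state`; `path` file path.
#' @export
write_grank_state <- function(state, path) {
  saveRDS(state, path)
  invisible(path)
}

#' @rdname write_grank_state
#' @export
read_grank_state <- function(path) {
  st <- readRDS(path)
  if (!inherits(st, "grank_state"))
    grank_stop("file does not contain a grank_state", "grank_config_error")
  st
}
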