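## Network-level contracts: agreement of the vectorized propagation and
## feed-forward updates with naive per-node loop oracles, E(3) invariance of
## the score, permutation invariance, batching independence, and
## checkpointing.

small_state <- function(seed = 21L, n_blocks = 2L) {
  st <- grank_init(grank_config(node_dims = c(6L, 2L), edge_dims = c(5L, 1L),
                                n_blocks = n_blocks, n_rbf = 4L,
                                dense_hidden = 4L, dropout_rate = 0.1,
                                seed = seed))
  ## non-trivial head so score-level checks are not comparing zeros
  randomize_head(st)
}

test_that("eval-mode propagation matches a naive per-node loop oracle", {
  set.seed(22)
  st <- small_state()
  msg_chain <- st$params$blocks[[1L]]$msg
  for (rep in 1:20) {
    g <- random_graph(n_nodes = sample(4:20, 1L))
    n <- nrow(g$coords)
    s <- matrix(rnorm(n * 6L), n)
    V <- matrix(rnorm(3L * n * 2L), 3L * n)
    es <- matrix(rnorm(nrow(g$edges) * 5L), nrow(g$edges))
    eV <- matrix(rnorm(3L * nrow(g$edges)), ncol = 1L)
    out <- grank:::propagate_forward(s, V, es, eV, g$edges, n, msg_chain,
                                     rate = 0, training = FALSE)
    ref <- ref_propagate(s, V, es, eV, g$edges, msg_chain)
    expect_lt(max(abs(out$s - ref$s)), 1e-6)
    expect_lt(max(abs(out$V - ref$V)), 1e-6)
  }
})

test_that("an isolated node's update is LayerNorm of its own embedding", {
  set.seed(23)
  st <- small_state()
  msg_chain <- st$params$blocks[[1L]]$msg
  ## two nodes, one directed pair among them, third node isolated
  edges <- rbind(c(1L, 2L), c(2L, 1L))
  n <- 3L
  s <- matrix(rnorm(n * 6L), n)
  V <- matrix(rnorm(3L * n * 2L), 3L * n)
  es <- matrix(rnorm(2L * 5L), 2L)
  eV <- matrix(rnorm(6L), ncol = 1L)
  out <- grank:::propagate_forward(s, V, es, eV, edges, n, msg_chain,
                                   rate = 0, training = FALSE)
  iso <- grank:::ln_forward(s[3L, , drop = FALSE],
                            grank:::v_gather(V, 3L, n), 1L)
  expect_equal(out$s[3L, ], as.numeric(iso$s), tolerance = 1e-12)
  expect_equal(grank:::v_gather(out$V, 3L, n), iso$V, tolerance = 1e-12)
})

test_that("eval-mode feed-forward matches per-node composition and is
           point-wise", {
  set.seed(24)
  st <- small_state()
  ff_chain <- st$params$blocks[[1L]]$ff
  n <- 9L
  s <- matrix(rnorm(n * 6L), n)
  V <- matrix(rnorm(3L * n * 2L), 3L * n)
  out <- grank:::ff_forward(s, V, ff_chain, rate = 0, training = FALSE, n)
  ref <- ref_feed_forward(s, V, ff_chain)
  expect_lt(max(abs(out$s - ref$s)), 1e-6)
  expect_lt(max(abs(out$V - ref$V)), 1e-6)

  ## permuting nodes permutes outputs identically
  perm <- sample(n)
  sp <- s[perm, , drop = FALSE]
  Vp <- grank:::v_gather(V, perm, n)
  outp <- grank:::ff_forward(sp, Vp, ff_chain, rate = 0, training = FALSE, n)
  expect_equal(outp$s, out$s[perm, , drop = FALSE], tolerance = 1e-12)
  expect_equal(outp$V, grank:::v_gather(out$V, perm, n), tolerance = 1e-12)
})

test_that("the score is invariant under rigid transforms including
           reflections", {
  set.seed(25)
  cc <- random_cloud_complex(n_per = 10L, gap = 2)
  cc <- filter_elements(cc)
  g0 <- build_graph(cc, n_rbf = 4L)
  st <- small_state()
  base <- score_graph(g0, st)
  worst <- 0
  for (rep in 1:40) {
    R <- random_rotation(proper = rep %% 2L == 1L)
    t <- rnorm(3L, sd = 30)
    g1 <- build_graph(transform_complex(cc, R, t), n_rbf = 4L)
    worst <- max(worst, abs(score_graph(g1, st) - base))
  }
  expect_lt(worst, 1e-4)
})

test_that("the score is invariant under node reordering", {
  set.seed(26)
  st <- small_state()
  for (rep in 1:10) {
    cc <- random_cloud_complex(n_per = 8L, gap = 2)
    base <- score_graph(build_graph(cc, n_rbf = 4L), st)
    perm <- sample(nrow(cc$atoms))
    cc2 <- cc
    cc2$atoms <- cc$atoms[perm, , drop = FALSE]
    expect_equal(score_graph(build_graph(cc2, n_rbf = 4L), st), base,
                 tolerance = 1e-6)
  }
})

test_that("scores do not depend on batch composition", {
  set.seed(27)
  st <- small_state()
  graphs <- lapply(1:6, function(i) {
    g <- random_graph(n_nodes = sample(5:15, 1L))
    g$complex_id <- "c"; g$model_id <- paste0("m", i)
    g
  })
  alone <- vapply(graphs, function(g) score_graph(g, st), numeric(1L))
  together <- grank_forward(build_batch(graphs), st)$scores
  expect_equal(together, alone, tolerance = 1e-6)
})

test_that("a saved state reloads bit-exactly and reproduces scores", {
  set.seed(28)
  st <- small_state()
  g <- random_graph(10L)
  path <- tempfile(fileext = ".rds")
  write_grank_state(st, path)
  st2 <- read_grank_state(path)
  expect_identical(st2$params, st$params)
  expect_identical(score_graph(g, st2), score_graph(g, st))
})

test_that("a single-node graph's score is the dense head applied to that
           node's output-GVP scalars", {
  set.seed(29)
  st <- small_state()
  atoms <- data.frame(element = "C", atom_name = "C1", residue_name = "GLY",
                      chain_id = "A", residue_seq = 1L, icode = "",
                      x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  cc <- structure(list(complex_id = "s", model_id = "m", receptor_chain = "A",
                       ligand_chain = "B", atoms = atoms),
                  class = "chain_complex")
  g <- build_graph(cc, n_rbf = 4L)
  got <- score_graph(g, st)
  ## hand-composed forward pass: input GVP -> blocks (zero messages) ->
  ## output GVP -> dense head
  p <- st$params
  h <- grank:::gvp_forward(g$node_scalar, matrix(0, 3L, 1L), p$node_in)
  s <- h$s; V <- h$V
  for (b in seq_along(p$blocks)) {
    ln1 <- grank:::ln_forward(s, V, 1L)
    f <- grank:::chain_forward(ln1$s, ln1$V, p$blocks[[b]]$ff)
    ln2 <- grank:::ln_forward(ln1$s + f$s, ln1$V + f$V, 1L)
    s <- ln2$s; V <- ln2$V
  }
  o <- grank:::gvp_forward(s, V, p$out_gvp)
  h1 <- pmax(o$s %*% t(p$dense1$W) + p$dense1$b, 0)
  expected <- as.numeric(h1 %*% t(p$dense2$W) + p$dense2$b)
  expect_equal(got, expected, tolerance = 1e-9)
})

test_that("eval-mode forward is deterministic; train mode dropout is seeded", {
  set.seed(30)
  st <- small_state()
  g <- random_graph(12L)
  expect_identical(score_graph(g, st), score_graph(g, st))
  set.seed(99); a <- score_graph(g, st, mode = "train")
  set.seed(99); b <- score_graph(g, st, mode = "train")
  expect_identical(a, b)
})

test_that("full-network analytic gradients match finite differences", {
  set.seed(31)
  st <- small_state()
  nat <- make_native(decoy_recipe(n_res_per_chain = 3L, seed = 2L), "gc")
  g1 <- featurize_complex(nat, n_rbf = 4L)
  g2 <- featurize_complex(make_decoy(nat, 1, 5, seed = 3L, model_id = "m"),
                          n_rbf = 4L)
  b <- build_batch(list(g1, g2))
  y <- c(0.8, 0.3)
  loss <- function(state) mean((grank_forward(b, state)$scores - y)^2)
  fw <- grank_forward(b, st, keep_cache = TRUE)
  gr <- grank:::grank_backward(2 * (fw$scores - y) / 2, st, fw$cache)
  h <- 1e-5
  probes <- list(c("dense2", "W"), c("dense1", "W"), c("out_gvp", "Ws"),
                 c("node_in", "Wh"), c("edge_in", "Wmu"),
                 list("blocks", 1L, "msg", 1L, "Ws"),
                 list("blocks", 1L, "msg", 3L, "Wg"),
                 list("blocks", 2L, "msg", 2L, "Wn"),
                 list("blocks", 2L, "ff", 1L, "Wmu"),
                 list("blocks", 1L, "ff", 2L, "bm"))
  for (path in probes) {
    leaf <- st$params
    for (k in path) leaf <- leaf[[k]]
    gleaf <- gr
    for (k in path) gleaf <- gleaf[[k]]
    for (ii in sample(length(leaf), min(3L, length(leaf)))) {
      perturb <- function(delta) {
        s2 <- st
        node <- paste0(
          "s2$params",
          paste(vapply(path, function(k) {
            if (is.character(k)) sprintf("[[\"%s\"]]", k)
            else sprintf("[[%d]]", k)
          }, ""), collapse = ""))
        eval(parse(text = sprintf("%s[ii] <- %s[ii] + delta", node, node)))
        s2
      }
      num <- (loss(perturb(h)) - loss(perturb(-h))) / (2 * h)
      expect_equal(gleaf[ii], num, tolerance = 1e-4,
                   label = sprintf("d loss / d %s[%d]",
                                   paste(unlist(path), collapse = "/"), ii))
    }
  }
})
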