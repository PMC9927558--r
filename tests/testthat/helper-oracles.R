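## Independent reference implementations used as test oracles. These are
## deliberately naive (plain loops, O(n^2) scans) and share no code with the
## package's vectorized paths.

## all pairs (i < j) within cutoff, by exhaustive scan
brute_pairs <- function(coords, cutoff) {
  n <- nrow(coords)
  out <- matrix(integer(0), ncol = 2L)
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <= cutoff)
        out <- rbind(out, c(i, j))
    }
  }
  out
}

## random proper rotation via QR; reflection optionally forced
random_rotation <- function(proper = TRUE) {
  qr_d <- qr(matrix(rnorm(9L), 3L))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  if (!proper) R[, 1L] <- -R[, 1L]
  R
}

## apply a rigid (or reflecting) transform to a chain_complex
transform_complex <- function(cc, R, t = c(0, 0, 0)) {
  xyz <- as.matrix(cc$atoms[, c("x", "y", "z")])
  cc$atoms[, c("x", "y", "z")] <- sweep(xyz %*% t(R), 2L, t, "+")
  cc
}

## node i's vector channels of an axis-major matrix, as an nv x 3 matrix
node_vectors <- function(V, i, n) {
  t(V[c(i, n + i, 2L * n + i), , drop = FALSE])
}

## pack a list of per-node nv x 3 matrices into the axis-major layout
pack_vectors <- function(vlist) {
  n <- length(vlist)
  nv <- nrow(vlist[[1L]])
  V <- matrix(0, 3L * n, nv)
  for (i in seq_len(n)) V[c(i, n + i, 2L * n + i), ] <- t(vlist[[i]])
  V
}

## reference single-tuple GVP: s a numeric vector, V an nv x 3 matrix
ref_gvp <- function(s, V, p) {
  act <- isTRUE(attr(p, "activate"))
  s_pre <- as.numeric(p$Ws %*% s + p$bm)
  Vh <- NULL
  if (!is.null(p$Wh)) {
    Vh <- p$Wh %*% V                       # h x 3
    nrm <- sqrt(rowSums(Vh^2))
    s_pre <- s_pre + as.numeric(p$Wn %*% nrm)
  }
  s_out <- if (act) pmax(s_pre, 0) else s_pre
  V_out <- NULL
  if (!is.null(p$Wmu)) {
    Vmu <- p$Wmu %*% Vh
    gate <- 1 / (1 + exp(-(as.numeric(p$Wg %*% s_pre + p$bg))))
    V_out <- Vmu * gate
  }
  list(s = s_out, V = V_out)
}

ref_gvp_chain <- function(s, V, chain) {
  for (p in chain) {
    out <- ref_gvp(s, V, p)
    s <- out$s; V <- out$V
  }
  list(s = s, V = V)
}

## reference tuple LayerNorm matching the package's conventions
ref_ln <- function(s, V, eps = 1e-6) {
  mu <- mean(s)
  s_out <- (s - mu) / sqrt(mean((s - mu)^2) + eps)
  V_out <- NULL
  if (!is.null(V)) V_out <- V / sqrt(mean(rowSums(V^2)) + eps)
  list(s = s_out, V = V_out)
}

## reference per-node propagation update (Eq.-style loop, no scatter ops)
ref_propagate <- function(graph_s, graph_V, edge_s, edge_V, edges, msg_chain) {
  n <- nrow(graph_s)
  out_s <- graph_s * 0
  nv <- ncol(graph_V)
  out_V <- graph_V * 0
  for (i in seq_len(n)) {
    inc <- which(edges[, 2L] == i)
    hs <- graph_s[i, ]
    hV <- node_vectors(graph_V, i, n)
    if (length(inc)) {
      msum_s <- NULL; msum_V <- NULL
      for (e in inc) {
        j <- edges[e, 1L]
        m <- ref_gvp_chain(
          c(graph_s[j, ], edge_s[e, ]),
          rbind(node_vectors(graph_V, j, n),
                node_vectors(edge_V, e, nrow(edges))),
          msg_chain)
        msum_s <- if (is.null(msum_s)) m$s else msum_s + m$s
        msum_V <- if (is.null(msum_V)) m$V else msum_V + m$V
      }
      hs <- hs + msum_s / length(inc)
      hV <- hV + msum_V / length(inc)
    }
    ln <- ref_ln(hs, hV)
    out_s[i, ] <- ln$s
    out_V[c(i, n + i, 2L * n + i), ] <- t(ln$V)
  }
  list(s = out_s, V = out_V)
}

## reference per-node feed-forward update
ref_feed_forward <- function(graph_s, graph_V, ff_chain) {
  n <- nrow(graph_s)
  out_s <- graph_s * 0
  out_V <- graph_V * 0
  for (i in seq_len(n)) {
    f <- ref_gvp_chain(graph_s[i, ], node_vectors(graph_V, i, n), ff_chain)
    ln <- ref_ln(graph_s[i, ] + f$s, node_vectors(graph_V, i, n) + f$V)
    out_s[i, ] <- ln$s
    out_V[c(i, n + i, 2L * n + i), ] <- t(ln$V)
  }
  list(s = out_s, V = out_V)
}

## random small point-cloud complex: two chains of n_per atoms each
random_cloud_complex <- function(n_per = 8L, spread = 6, gap = 4) {
  xyz <- rbind(matrix(runif(n_per * 3L, 0, spread), ncol = 3L),
               sweep(matrix(runif(n_per * 3L, 0, spread), ncol = 3L),
                     2L, c(0, 0, spread + gap - spread), "+"))
  atoms <- data.frame(
    element = sample(c("C", "N", "O", "S", "H"), 2L * n_per, replace = TRUE),
    atom_name = paste0("X", seq_len(2L * n_per)),
    residue_name = "GLY",
    chain_id = rep(c("A", "B"), each = n_per),
    residue_seq = rep(seq_len(n_per), 2L),
    icode = "",
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    stringsAsFactors = FALSE
  )
  grank:::new_chain_complex("rand", "m", "A", "B", atoms)
}

## small graph with random tuple features for network-level oracles
random_graph <- function(n_nodes = 8L, n_rbf = 4L, box = 6) {
  repeat {
    coords <- matrix(runif(n_nodes * 3L, 0, box), ncol = 3L)
    if (min(dist(coords)) > 1e-3) break
  }
  atoms <- data.frame(
    element = sample(c("C", "N", "O", "S", "H"), n_nodes, replace = TRUE),
    atom_name = paste0("X", seq_len(n_nodes)), residue_name = "GLY",
    chain_id = c("A", rep_len(c("A", "B"), n_nodes - 2L), "B"),
    residue_seq = seq_len(n_nodes), icode = "",
    x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
    stringsAsFactors = FALSE
  )
  cc <- grank:::new_chain_complex("toy", "g", "A", "B", atoms)
  build_graph(cc, edge_cutoff = 4.5, n_rbf = n_rbf)
}

## column-exact ATOM line (columns 13-16 atom name, 17 altloc, 18-20 residue,
## 22 chain, 23-26 resseq, 31-54 coords, 77-78 element)
pdb_line <- function(serial, name, resname, chain, resseq, x, y, z,
                     elem = "", altloc = " ") {
  name4 <- if (nchar(name) >= 4L) substr(name, 1L, 4L)
           else sprintf(" %-3s", name)
  sprintf("ATOM  %5d %s%s%-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name4, altloc, resname, chain, resseq, x, y, z, elem)
}

## minimal two-chain PDB text: one CA per chain at given z separation
two_atom_pdb <- function(dz) {
  c(sprintf("ATOM      1  CA  ALA A   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
            0, 0, 0),
    sprintf("ATOM      2  CA  ALA B   1    %8.3f%8.3f%8.3f  1.00  0.00           C",
            0, 0, dz))
}

## give an untrained state a non-trivial output head (the head is
## zero-initialized for training, which would make score-level symmetry and
## protocol checks vacuous on random states)
randomize_head <- function(st, sd = 0.2) {
  st$params$dense2$W[] <- rnorm(length(st$params$dense2$W), sd = sd)
  st$params$dense2$b <- rnorm(1L, sd = sd)
  st
}
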