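#' Atoms participating in the inter-chain interface
#'
#' An atom belongs to the interface when it has at least one atom of the
#' *other* chain within `cutoff` angstrom (default 8.5, the graph-extraction
#' cutoff). Symmetric in the two chains; returns indices into the complex's
#' atom table.
#'
#' @param complex a `chain_complex` (element-filtered for featurization use).
#' @param cutoff contact cutoff in angstrom, inclusive.
#' @return sorted integer vector of atom indices (possibly empty).
#' @export
find_contact_atoms <- function(complex, cutoff = 8.5) {
  coords <- complex_coords(complex)
  is_rec <- complex$atoms$chain_id == complex$receptor_chain
  pairs <- neighbor_pairs(coords, cutoff)
  if (nrow(pairs) == 0L) return(integer(0))
  cross <- is_rec[pairs[, 1L]] != is_rec[pairs[, 2L]]
  sort(unique(as.integer(pairs[cross, ])))
}

#' Restrict a complex to its interface atoms
#'
#' Subsets the complex to the atoms returned by [find_contact_atoms()],
#' preserving atom order, and records how many atoms were dropped. Models with
#' an empty contact set cannot be scored and raise a
#' `grank_no_contact_error`, which dataset assembly catches to exclude the
#' model.
#'
#' @inheritParams find_contact_atoms
#' @return the interface `chain_complex`, with attribute `n_dropped`.
#' @export
extract_interface <- function(complex, cutoff = 8.5) {
  idx <- find_contact_atoms(complex, cutoff)
  if (!length(idx))
    grank_stop(sprintf(
      "no contact atoms within %.1f angstrom for model '%s' of complex '%s'",
      cutoff, complex$model_id, complex$complex_id), "grank_no_contact_error")
  dropped <- nrow(complex$atoms) - length(idx)
  complex$atoms <- complex$atoms[idx, , drop = FALSE]
  rownames(complex$atoms) <- NULL
  attr(complex, "n_dropped") <- dropped
  complex
}

#' One-hot encoding of an atom element
#'
#' Canonical slot order C, N, O, S, H.
#'
#' @param element character vector of element symbols.
#' @return length(element) x 5 matrix with one 1 per row.
#' @export
one_hot_atom <- function(element) {
  slot <- match(element, GRANK_ELEMENTS)
  if (anyNA(slot))
    grank_stop(sprintf("element '%s' is not one of C,N,O,S,H",
                       element[which(is.na(slot))[1L]]),
               "grank_element_error")
  m <- matrix(0, length(element), 5L,
              dimnames = list(NULL, GRANK_ELEMENTS))
  m[cbind(seq_along(element), slot)] <- 1
  m
}

#' Gaussian radial-basis centers and width for edge-length encoding
#' @noRd
rbf_centers <- function(n_rbf, d_max) {
  mu <- seq(0, d_max, length.out = n_rbf)
  list(mu = mu, sigma = mu[2L] - mu[1L])
}

#' Geometric edge features: distance RBF and unit direction
#'
#' For an edge j -> i the scalar feature is a Gaussian radial basis expansion
#' of the length, `rbf_k = exp(-(d - mu_k)^2 / (2 sigma^2))` with `n_rbf`
#' centers evenly spaced on `[0, d_max]` and `sigma` equal to the center
#' spacing; the vector feature is the unit vector from source j to target i.
#'
#' @param coord_i,coord_j 3-vectors (target i, source j), angstrom.
#' @param n_rbf number of Gaussian basis functions.
#' @param d_max upper end of the center grid (the edge cutoff), angstrom.
#' @return list with `rbf` (length `n_rbf`) and `unit` (3-vector, norm 1).
#' @export
encode_edge <- function(coord_i, coord_j, n_rbf = 16L, d_max = 4.5) {
  delta <- coord_i - coord_j
  d <- sqrt(sum(delta^2))
  if (d == 0)
    grank_stop("zero-length edge: duplicate atom coordinates",
               "grank_degenerate_edge_error")
  cen <- rbf_centers(n_rbf, d_max)
  list(rbf = exp(-(d - cen$mu)^2 / (2 * cen$sigma^2)), unit = delta / d)
}

#' Build the atom-level interface graph of a docking model
#'
#' Nodes are the atoms of the (already interface-extracted, element-filtered)
#' complex in input order; directed edges j -> i connect every ordered pair of
#' distinct atoms within `edge_cutoff` angstrom (both directions present, no
#' self loops, intra- and inter-chain pairs alike). Node scalars are the
#' one-hot atom type; edge scalars are the RBF-encoded length and the edge
#' vector is the unit direction from source to target.
#'
#' Vector-valued features are stored axis-major: a matrix with `3n` rows where
#' rows `1..n` are x components, `n+1..2n` y and `2n+1..3n` z.
#'
#' @param complex a `chain_complex` with at least one atom.
#' @param edge_cutoff edge distance cutoff in angstrom (default 4.5).
#' @param n_rbf number of radial basis functions (default 16).
#' @return an `interface_graph`: list with `coords` (n x 3), `node_scalar`
#'   (n x 5), `edges` (E x 2 integer matrix, columns src j / dst i),
#'   `edge_scalar` (E x n_rbf), `edge_vector` (3E x 1, axis-major),
#'   `chain` (per-node chain id), and the complex/model ids.
#' @export
build_graph <- function(complex, edge_cutoff = 4.5, n_rbf = 16L) {
  coords <- complex_coords(complex)
  n <- nrow(coords)
  if (n == 0L) grank_stop("cannot build a graph with zero atoms",
                          "grank_empty_graph_error")
  und <- neighbor_pairs(coords, edge_cutoff)
  ## both directions: (src, dst)
  edges <- rbind(und, und[, c(2L, 1L), drop = FALSE])
  if (nrow(edges)) {
    edges <- edges[order(edges[, 2L], edges[, 1L]), , drop = FALSE]
    delta <- coords[edges[, 2L], , drop = FALSE] -
      coords[edges[, 1L], , drop = FALSE]           # target i minus source j
    d <- sqrt(rowSums(delta^2))
    if (any(d == 0))
      grank_stop("zero-length edge: duplicate atom coordinates",
                 "grank_degenerate_edge_error")
    cen <- rbf_centers(n_rbf, edge_cutoff)
    edge_scalar <- exp(-(outer(d, cen$mu, "-"))^2 / (2 * cen$sigma^2))
    unit <- delta / d
    edge_vector <- matrix(as.numeric(unit), ncol = 1L)  # axis-major (3E x 1)
  } else {
    edge_scalar <- matrix(numeric(0), 0L, n_rbf)
    edge_vector <- matrix(numeric(0), 0L, 1L)
  }
  structure(
    list(coords = coords,
         node_scalar = one_hot_atom(complex$atoms$element),
         edges = edges,
         edge_scalar = edge_scalar,
         edge_vector = edge_vector,
         chain = complex$atoms$chain_id,
         complex_id = complex$complex_id,
         model_id = complex$model_id),
    class = "interface_graph"
  )
}

#' @export
print.interface_graph <- function(x, ...) {
  cat(sprintf("<interface_graph %s/%s> %d nodes, %d directed edges\n",
              x$complex_id, x$model_id, nrow(x$coords), nrow(x$edges)))
  invisible(x)
}

#' Full featurization of one docking model
#'
#' Convenience chain: element filter -> 8.5 angstrom interface extraction ->
#' 4.5 angstrom graph construction.
#'
#' @inheritParams build_graph
#' @param interface_cutoff interface extraction cutoff, angstrom.
#' @export
featurize_complex <- function(complex, interface_cutoff = 8.5,
                              edge_cutoff = 4.5, n_rbf = 16L) {
  complex <- filter_elements(complex)
  complex <- extract_interface(complex, cutoff = interface_cutoff)
  build_graph(complex, edge_cutoff = edge_cutoff, n_rbf = n_rbf)
}
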