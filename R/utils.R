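## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Stop with a classed condition so callers can catch specific failures.
#' @noRd
grank_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "grank_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

## Derive a child seed from a parent seed and a stream index, staying inside
## the 32-bit integer range R requires for set.seed().
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 16807 + 12345) %%
               2147483647)
}

## Squared pairwise distances between two coordinate matrices (rows = points).
cross_dist2 <- function(a, b) {
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' All point pairs within a distance cutoff, via a cell list
#'
#' Bins points into a uniform grid with cell side equal to the cutoff so only
#' the 27 neighbouring cells of each occupied cell need to be scanned;
#' expected linear time for bounded-density point clouds.
#'
#' @param coords numeric matrix, one 3D point per row (angstrom).
#' @param cutoff distance cutoff in angstrom (inclusive).
#' @return two-column integer matrix of pairs (i, j) with i < j and
#'   distance(i, j) <= cutoff. Zero rows when no pair qualifies.
#' @keywords internal
neighbor_pairs <- function(coords, cutoff) {
  n <- nrow(coords)
  empty <- matrix(integer(0), ncol = 2L)
  if (n < 2L) return(empty)
  cell <- floor(sweep(coords, 2L, apply(coords, 2L, min)) / cutoff)
  ## pack 3D cell index into one key (coordinates are bounded, offsets small)
  nx <- max(cell[, 1L]) + 3L
  ny <- max(cell[, 2L]) + 3L
  key <- function(cx, cy, cz) (cz * ny + cy) * nx + cx + 1
  pkey <- key(cell[, 1L], cell[, 2L], cell[, 3L])
  buckets <- split(seq_len(n), pkey)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  out <- vector("list", length(buckets) * 14L)
  m <- 0L
  cut2 <- cutoff^2
  for (b in buckets) {
    ck <- cell[b[1L], ]
    for (r in seq_len(nrow(offsets))) {
      nk <- key(ck[1L] + offsets[r, 1L], ck[2L] + offsets[r, 2L],
                ck[3L] + offsets[r, 3L])
      same <- offsets[r, 1L] == 0L && offsets[r, 2L] == 0L && offsets[r, 3L] == 0L
      if (same) {
        if (length(b) < 2L) next
        cand <- cbind(rep(b, times = length(b)), rep(b, each = length(b)))
        cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
      } else {
        nb <- buckets[[as.character(nk)]]
        if (is.null(nb)) next
        ## scan each unordered cell pair once
        if (nk < pkey[b[1L]]) next
        cand <- cbind(rep(b, times = length(nb)), rep(nb, each = length(b)))
      }
      if (nrow(cand) == 0L) next
      d2 <- rowSums((coords[cand[, 1L], , drop = FALSE] -
                       coords[cand[, 2L], , drop = FALSE])^2)
      keep <- d2 <= cut2
      if (any(keep)) {
        m <- m + 1L
        cc <- cand[keep, , drop = FALSE]
        swap <- cc[, 1L] > cc[, 2L]
        if (any(swap)) cc[swap, ] <- cc[swap, c(2L, 1L), drop = FALSE]
        out[[m]] <- cc
      }
    }
  }
  if (m == 0L) return(empty)
  res <- unique(do.call(rbind, out[seq_len(m)]))
  res[order(res[, 1L], res[, 2L]), , drop = FALSE]
}
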