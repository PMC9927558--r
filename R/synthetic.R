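## Synthetic two-chain complexes and rigid-body-perturbed decoys. The
## generator emulates the shape of a docking benchmark — one native complex
## per target plus a pool of decoys whose interface quality spans the full
## f-nat range — while staying small enough that labeling, featurization,
## training and evaluation all run in seconds. Perturbations are rigid-body
## only, so the geometry-to-f-nat relationship stays analytic (e.g. the lRMSD
## of a pure-translation decoy equals the translation magnitude exactly).

#' Recipe for a synthetic native complex
#'
#' Each chain is a gently curved self-avoiding coarse backbone with residues
#' spaced 3.8 angstrom (the CA-CA distance of real protein chains). Every
#' residue carries the four backbone atoms N, CA, C, O, `atoms_per_res - 4`
#' side-chain pseudo-atoms whose elements are drawn with fixed probabilities
#' (C 0.6, N 0.15, O 0.2, S 0.05) so every one-hot slot is exercised, and
#' optionally one amide hydrogen at a fixed offset. The ligand chain is
#' placed facing the receptor and slid along the inter-chain axis until the
#' closest heavy-atom pair sits at ~3.2 angstrom (van-der-Waals contact),
#' which guarantees a dense contact interface at zero perturbation.
#'
#' @param n_res_per_chain residues per chain (>= 3). The default of 8 gives
#'   miniature complexes whose interfaces carry a realistically dense contact
#'   set (~15-25 native residue contacts), so f-nat varies almost
#'   continuously across decoys.
#' @param atoms_per_res heavy atoms per residue (>= 4: N, CA, C, O plus
#'   side-chain pseudo-atoms).
#' @param add_hydrogens add one amide H per residue at a fixed offset.
#' @param seed integer seed; the same recipe always builds the same native.
#' @return a `decoy_recipe` list.
#' @export
decoy_recipe <- function(n_res_per_chain = 8L, atoms_per_res = 5L,
                         add_hydrogens = TRUE, seed = 1L) {
  stopifnot(n_res_per_chain >= 3L, atoms_per_res >= 4L)
  structure(list(n_res_per_chain = as.integer(n_res_per_chain),
                 atoms_per_res = as.integer(atoms_per_res),
                 add_hydrogens = isTRUE(add_hydrogens),
                 seed = as.integer(seed)),
            class = "decoy_recipe")
}

## one chain along +x with mild helical wobble; returns an atom data frame
build_chain <- function(recipe, chain_id, phase) {
  n <- recipe$n_res_per_chain
  rows <- vector("list", n)
  n_side <- recipe$atoms_per_res - 4L
  side_elems <- if (n_side > 0L)
    matrix(sample(c("C", "N", "O", "S"), n * n_side, replace = TRUE,
                  prob = c(0.6, 0.15, 0.2, 0.05)), nrow = n)
  for (i in seq_len(n)) {
    ## mild in-plane wobble keeps the chain self-avoiding; the out-of-plane
    ## amplitude stays small so the chain presents a flat face to its partner
    ## and the interface is contact-dense
    ca <- c(3.8 * i, 0.8 * sin(0.9 * i + phase), 0.1 * cos(0.9 * i + phase))
    atoms <- rbind(
      N  = ca + c(-1.2, 0.9, 0.1),
      CA = ca,
      C  = ca + c(1.3, 0.8, -0.1),
      O  = ca + c(1.5, 1.9, -0.3)
    )
    elements <- c("N", "C", "C", "O")
    names <- c("N", "CA", "C", "O")
    if (n_side > 0L) {
      for (sdx in seq_len(n_side)) {
        atoms <- rbind(atoms, ca + c(0.2 * sdx - 0.1, -1.1 * sdx, 1.0))
        elements <- c(elements, side_elems[i, sdx])
        names <- c(names, paste0("X", sdx))
      }
    }
    if (recipe$add_hydrogens) {
      atoms <- rbind(atoms, atoms[1L, ] + c(-0.3, 0.9, 0.2))
      elements <- c(elements, "H")
      names <- c(names, "H")
    }
    rows[[i]] <- data.frame(
      element = elements, atom_name = names,
      residue_name = "GLY", chain_id = chain_id,
      residue_seq = i, icode = "",
      x = atoms[, 1L], y = atoms[, 2L], z = atoms[, 3L],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a synthetic native two-chain complex
#'
#' @param recipe a [decoy_recipe()].
#' @param complex_id identifier stamped on the complex.
#' @return a `chain_complex` with receptor chain "A" and ligand chain "B",
#'   guaranteed to have inter-chain heavy-atom contacts within 5 angstrom.
#' @export
make_native <- function(recipe = decoy_recipe(), complex_id = "synth") {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(recipe$seed)
  rec <- build_chain(recipe, "A", phase = 0)
  lig <- build_chain(recipe, "B", phase = 1.1)
  ## face the receptor: flip the ligand about the x axis, then approach in +z
  lig$y <- -lig$y
  lig$z <- -lig$z
  rec_xyz <- as.matrix(rec[rec$element != "H", c("x", "y", "z")])
  lig_xyz <- as.matrix(lig[lig$element != "H", c("x", "y", "z")])
  ## slide apart until the closest heavy-atom pair reaches van-der-Waals
  ## contact distance (~3.2 angstrom): tight packing without clashes
  for (gap in seq(2, 30, by = 0.1)) {
    d2 <- cross_dist2(rec_xyz, sweep(lig_xyz, 2L, c(0, 0, gap), "+"))
    if (sqrt(min(d2)) >= 3.2) break
  }
  lig$z <- lig$z + gap
  atoms <- rbind(rec, lig)
  rownames(atoms) <- NULL
  new_chain_complex(complex_id, "native", "A", "B", atoms)
}

## rotation matrix: angle (radians) about a unit axis (Rodrigues)
rotation_about_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3L], -axis[2L],
                -axis[3L], 0, axis[1L],
                axis[2L], -axis[1L], 0), 3L, 3L)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Rigid-body decoy of a native complex
#'
#' Rotates the ligand chain about its centroid by `rotation` degrees around a
#' random axis, then translates it by `translation` angstrom along a random
#' direction; the receptor is untouched. Zero magnitudes return the native
#' geometry exactly.
#'
#' @param native a `chain_complex` from [make_native()].
#' @param translation translation magnitude, angstrom.
#' @param rotation rotation magnitude, degrees.
#' @param seed seed for the random axis and direction.
#' @param model_id identifier stamped on the decoy.
#' @return the perturbed `chain_complex`.
#' @export
make_decoy <- function(native, translation, rotation, seed,
                       model_id = "decoy") {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  is_lig <- native$atoms$chain_id == native$ligand_chain
  xyz <- as.matrix(native$atoms[is_lig, c("x", "y", "z")])
  if (rotation != 0) {
    axis <- stats::rnorm(3L)
    ctr <- colMeans(xyz)
    R <- rotation_about_axis(axis, rotation * pi / 180)
    xyz <- sweep(sweep(xyz, 2L, ctr) %*% t(R), 2L, ctr, "+")
  }
  if (translation != 0) {
    dir <- stats::rnorm(3L)
    dir <- dir / sqrt(sum(dir^2))
    xyz <- sweep(xyz, 2L, translation * dir, "+")
  }
  native$atoms[is_lig, c("x", "y", "z")] <- xyz
  native$model_id <- model_id
  native
}

#' Default perturbation magnitude grid
#'
#' Translations crossed with rotations, ordered by increasing severity, so
#' sampling the grid evenly spans f-nat from 1 down to 0.
#' @return data frame (translation, rotation).
#' @export
magnitude_grid_default <- function() {
  g <- expand.grid(translation = c(0, 0.5, 1, 2, 4, 8, 16),
                   rotation = c(0, 5, 15, 45))
  ## severity proxy: translation plus the arc displacement of a ~10 A lever
  sev <- g$translation + 10 * 2 * sin(g$rotation * pi / 360)
  g <- g[order(sev, g$translation, g$rotation), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Generate a complete synthetic decoy dataset
#'
#' Builds `n_complexes` synthetic natives and, for each, `n_decoys_per_complex`
#' rigid-body decoys with magnitudes spread evenly over the grid (always
#' including the unperturbed and the most-perturbed combination). Quality
#' labels are *computed* with the labeling machinery, not assumed from the
#' construction; decoys whose interface is empty at the graph-extraction
#' cutoff are excluded and counted, mirroring how models without contact
#' atoms are dropped from real benchmarks.
#'
#' @param n_complexes,n_decoys_per_complex dataset dimensions.
#' @param magnitude_grid data frame (translation, rotation); default
#'   [magnitude_grid_default()].
#' @param seed master seed; every native and decoy derives its own stream.
#' @param recipe a [decoy_recipe()] (its seed field is overridden per
#'   complex).
#' @param interface_cutoff,edge_cutoff,n_rbf featurization parameters.
#' @return list with `graphs` (interface graphs of the retained decoys),
#'   `labels` (their quality labels, aligned), `manifest` (complex/model
#'   table), `decoys` (the retained decoy complexes), `natives` (list of
#'   native complexes) and `n_excluded`.
#' @export
make_dataset <- function(n_complexes = 40L, n_decoys_per_complex = 20L,
                         magnitude_grid = magnitude_grid_default(),
                         seed = 1L, recipe = decoy_recipe(),
                         interface_cutoff = 8.5, edge_cutoff = 4.5,
                         n_rbf = 16L) {
  stopifnot(n_complexes >= 1L, n_decoys_per_complex >= 2L)
  combo <- round(seq(1L, nrow(magnitude_grid),
                     length.out = n_decoys_per_complex))
  graphs <- list(); labels <- list(); manifest <- list(); decoys <- list()
  natives <- vector("list", n_complexes)
  n_excluded <- 0L
  for (c_i in seq_len(n_complexes)) {
    cid <- sprintf("synth%03d", c_i)
    recipe$seed <- derive_seed(seed, c_i)
    native <- make_native(recipe, complex_id = cid)
    natives[[c_i]] <- native
    nset <- native_contacts(native)
    for (d_i in seq_len(n_decoys_per_complex)) {
      mg <- magnitude_grid[combo[d_i], ]
      mid <- sprintf("decoy%03d", d_i)
      decoy <- make_decoy(native, mg$translation, mg$rotation,
                          seed = derive_seed(seed, c_i * 1000L + d_i),
                          model_id = mid)
      g <- tryCatch(
        featurize_complex(decoy, interface_cutoff = interface_cutoff,
                          edge_cutoff = edge_cutoff, n_rbf = n_rbf),
        grank_no_contact_error = function(e) NULL
      )
      if (is.null(g)) {
        n_excluded <- n_excluded + 1L
        next
      }
      fnat <- compute_fnat(decoy, nset)
      key <- paste0(cid, "/", mid)
      graphs[[key]] <- g
      decoys[[key]] <- decoy
      labels[[key]] <- data.frame(
        complex_id = cid, model_id = mid, fnat = fnat,
        lrmsd = compute_lrmsd(decoy, native),
        irmsd = compute_irmsd(decoy, native),
        translation = mg$translation, rotation = mg$rotation,
        stringsAsFactors = FALSE
      )
      manifest[[key]] <- data.frame(complex_id = cid, model_id = mid,
                                    stringsAsFactors = FALSE)
    }
  }
  labels <- do.call(rbind, unname(labels))
  labels$capri_class <- mapply(capri_class, labels$fnat, labels$irmsd,
                               labels$lrmsd)
  labels$is_positive <- binary_label(labels$fnat)
  rownames(labels) <- NULL
  list(graphs = unname(graphs), labels = labels,
       manifest = do.call(rbind, unname(manifest)),
       decoys = unname(decoys), natives = natives, n_excluded = n_excluded)
}
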