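## Ground-truth quality of docking models against the native structure:
## f-nat, ligand RMSD, interface RMSD, CAPRI class, binary near-native label.

residue_key <- function(atoms) {
  paste(atoms$chain_id, atoms$residue_seq, atoms$icode, sep = "|")
}

atom_key <- function(atoms) {
  paste(residue_key(atoms), atoms$atom_name, sep = "|")
}

## Cross-chain residue pairs with >= 1 heavy-atom pair <= cutoff.
## Returns a data frame (receptor_res, ligand_res) with set semantics.
contact_pairs <- function(complex, cutoff) {
  heavy <- complex$atoms$element != "H"
  atoms <- complex$atoms[heavy, , drop = FALSE]
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  is_rec <- atoms$chain_id == complex$receptor_chain
  pairs <- neighbor_pairs(coords, cutoff)
  if (nrow(pairs)) {
    cross <- is_rec[pairs[, 1L]] != is_rec[pairs[, 2L]]
    pairs <- pairs[cross, , drop = FALSE]
  }
  if (!nrow(pairs))
    return(data.frame(receptor_res = character(0), ligand_res = character(0)))
  rk <- residue_key(atoms)
  a <- pairs[, 1L]; b <- pairs[, 2L]
  rec_first <- is_rec[a]
  rec <- ifelse(rec_first, rk[a], rk[b])
  lig <- ifelse(rec_first, rk[b], rk[a])
  df <- unique(data.frame(receptor_res = rec, ligand_res = lig,
                          stringsAsFactors = FALSE))
  df[order(df$receptor_res, df$ligand_res), , drop = FALSE]
}

#' Native inter-chain residue contacts
#'
#' A native contact is a cross-chain residue pair with at least one heavy-atom
#' (non-hydrogen) pair within `contact_cutoff` angstrom (default 5, the CAPRI
#' convention). Hydrogens are graph nodes for scoring but are excluded from
#' quality labeling.
#'
#' @param native the native (reference) `chain_complex`.
#' @param contact_cutoff heavy-atom distance cutoff, angstrom, inclusive.
#' @return a `contact_set`: data frame with columns `receptor_res`,
#'   `ligand_res` (residue identities `chain|seq|icode`).
#' @export
native_contacts <- function(native, contact_cutoff = 5.0) {
  df <- contact_pairs(native, contact_cutoff)
  if (!nrow(df))
    grank_stop("native structure has no inter-chain contacts: invalid reference",
               "grank_no_native_contacts_error")
  structure(df, class = c("contact_set", "data.frame"))
}

#' Fraction of native contacts reproduced by a docking model
#'
#' f-nat is the number of native residue contacts also present in the model,
#' divided by the number of native contacts; it ranges from 0 (interface
#' destroyed) to 1 (perfect interface). Model and native must use the same
#' residue numbering.
#'
#' @param model a docking-model `chain_complex`.
#' @param native_set a `contact_set` from [native_contacts()].
#' @param contact_cutoff heavy-atom cutoff used to detect model contacts.
#' @return f-nat in `[0, 1]`.
#' @export
compute_fnat <- function(model, native_set, contact_cutoff = 5.0) {
  present <- unique(residue_key(model$atoms))
  missing <- setdiff(unique(c(native_set$receptor_res, native_set$ligand_res)),
                     present)
  if (length(missing))
    grank_stop(sprintf(
      "residue '%s' of the native contact set is absent from the model",
      missing[1L]), "grank_residue_mismatch_error")
  mod <- contact_pairs(model, contact_cutoff)
  nat_k <- paste(native_set$receptor_res, native_set$ligand_res, sep = "+")
  mod_k <- paste(mod$receptor_res, mod$ligand_res, sep = "+")
  sum(nat_k %in% mod_k) / length(nat_k)
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares optimal proper rotation (determinant +1) and translation
#' mapping `Q` onto `P`, via SVD of the cross-covariance with determinant
#' correction so reflections are never returned; the correction also breaks
#' ties deterministically for degenerate (collinear/coplanar) point sets.
#'
#' The fitted transform of a point q is `R %*% (q - centroid(Q)) +
#' centroid(P)`.
#'
#' @param P,Q n x 3 coordinate matrices (angstrom), rows corresponding.
#' @return list with `rotation` (3 x 3, det +1), `translation` (the transform
#'   above packaged as `t` with `x -> R x + t`), and `rmsd`, the minimized
#'   root-mean-square deviation.
#' @export
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q) || ncol(P) != 3L || ncol(Q) != 3L)
    grank_stop("P and Q must be n x 3 matrices of equal length",
               "grank_shape_error")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  H <- crossprod(Qc, Pc)                 # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1                     # fully degenerate: pick +1 branch
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fitted <- Qc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Pc - fitted)^2)))
  list(rotation = R, translation = as.numeric(cp - R %*% cq), rmsd = rmsd)
}

## Shared backbone atoms (N, CA, C, O) of a residue selection, matched by
## (chain, residue, atom name) between model and native. Returns the two
## coordinate matrices in matched order.
matched_backbone <- function(model, native, residues = NULL) {
  bb <- c("N", "CA", "C", "O")
  sel <- function(cc) {
    a <- cc$atoms[cc$atoms$atom_name %in% bb, , drop = FALSE]
    if (!is.null(residues)) a <- a[residue_key(a) %in% residues, , drop = FALSE]
    a
  }
  am <- sel(model); an <- sel(native)
  km <- atom_key(am); kn <- atom_key(an)
  shared <- intersect(kn, km)
  list(model  = as.matrix(am[match(shared, km), c("x", "y", "z")]),
       native = as.matrix(an[match(shared, kn), c("x", "y", "z")]),
       keys = shared)
}

#' Ligand RMSD of a docking model
#'
#' Superposes the model onto the native by the receptor-chain backbone
#' (N, CA, C, O) with [kabsch_superpose()], then evaluates the RMSD over the
#' ligand-chain backbone atoms without further fitting. Missing backbone atoms
#' (e.g. terminal O) are tolerated: the shared subset is used.
#'
#' @param model,native `chain_complex` objects with consistent naming.
#' @return lRMSD in angstrom.
#' @export
compute_lrmsd <- function(model, native) {
  rec <- residue_key(native$atoms)[native$atoms$chain_id == native$receptor_chain]
  lig <- residue_key(native$atoms)[native$atoms$chain_id == native$ligand_chain]
  mr <- matched_backbone(model, native, unique(rec))
  if (nrow(mr$model) < 3L)
    grank_stop("fewer than 3 shared receptor backbone atoms",
               "grank_too_few_atoms_error")
  fit <- kabsch_superpose(mr$native, mr$model)
  ml <- matched_backbone(model, native, unique(lig))
  if (!nrow(ml$model))
    grank_stop("no shared ligand backbone atoms", "grank_too_few_atoms_error")
  moved <- sweep(ml$model %*% t(fit$rotation), 2L, fit$translation, "+")
  sqrt(mean(rowSums((ml$native - moved)^2)))
}

#' Interface RMSD of a docking model
#'
#' Interface residues are the native residues (both chains) having any heavy
#' atom within `interface_cutoff` angstrom of the other chain (default 10, the
#' CAPRI convention). The model is optimally superposed onto the native over
#' the backbone atoms of those residues and the minimized RMSD is returned.
#'
#' @inheritParams compute_lrmsd
#' @param interface_cutoff heavy-atom cutoff defining interface residues.
#' @return iRMSD in angstrom.
#' @export
compute_irmsd <- function(model, native, interface_cutoff = 10.0) {
  cp <- contact_pairs(native, interface_cutoff)
  iface <- unique(c(cp$receptor_res, cp$ligand_res))
  mb <- matched_backbone(model, native, iface)
  if (nrow(mb$model) < 3L)
    grank_stop("fewer than 3 interface backbone atoms",
               "grank_too_few_atoms_error")
  kabsch_superpose(mb$native, mb$model)$rmsd
}

#' Default CAPRI quality criteria
#'
#' Each row gives the f-nat floor and the lRMSD / iRMSD ceilings of one class;
#' a model earns the class if `fnat >= fnat_min` and (`lrmsd <= lrmsd_max` or
#' `irmsd <= irmsd_max`). The best earned class wins; models earning none are
#' "incorrect".
#' @export
capri_criteria_default <- function() {
  data.frame(
    class = c("high", "medium", "acceptable"),
    fnat_min = c(0.5, 0.3, 0.1),
    lrmsd_max = c(1.0, 5.0, 10.0),
    irmsd_max = c(1.0, 2.0, 4.0),
    stringsAsFactors = FALSE
  )
}

#' CAPRI quality class of a docking model
#'
#' @param fnat fraction of native contacts in `[0, 1]`.
#' @param irmsd,lrmsd interface and ligand RMSD, angstrom.
#' @param criteria criteria table; see [capri_criteria_default()].
#' @return one of `"high"`, `"medium"`, `"acceptable"`, `"incorrect"`.
#' @export
capri_class <- function(fnat, irmsd, lrmsd, criteria = capri_criteria_default()) {
  for (r in seq_len(nrow(criteria))) {
    if (fnat >= criteria$fnat_min[r] &&
        (lrmsd <= criteria$lrmsd_max[r] || irmsd <= criteria$irmsd_max[r]))
      return(criteria$class[r])
  }
  "incorrect"
}

#' Binary near-native label
#'
#' A model is near-native (positive) when its f-nat reaches the cutoff
#' (default 0.3; the boundary itself counts as positive).
#'
#' @param fnat f-nat in `[0, 1]`.
#' @param cutoff near-native threshold.
#' @return logical.
#' @export
binary_label <- function(fnat, cutoff = 0.3) {
  if (any(!is.finite(fnat)) || any(fnat < 0) || any(fnat > 1))
    grank_stop("fnat must lie in [0, 1]", "grank_range_error")
  fnat >= cutoff
}

#' Quality labels for a set of docking models
#'
#' Computes f-nat, lRMSD, iRMSD, CAPRI class and the binary near-native label
#' of each model against one native reference.
#'
#' @param native the native `chain_complex`.
#' @param models list of model `chain_complex` objects.
#' @param contact_cutoff f-nat contact cutoff, angstrom.
#' @param fnat_cutoff near-native f-nat threshold.
#' @return data frame with one row per model: complex_id, model_id, fnat,
#'   lrmsd, irmsd, capri_class, is_positive.
#' @export
label_models <- function(native, models, contact_cutoff = 5.0,
                         fnat_cutoff = 0.3) {
  nset <- native_contacts(native, contact_cutoff)
  rows <- lapply(models, function(m) {
    fnat <- compute_fnat(m, nset, contact_cutoff)
    lr <- compute_lrmsd(m, native)
    ir <- compute_irmsd(m, native)
    data.frame(complex_id = m$complex_id, model_id = m$model_id,
               fnat = fnat, lrmsd = lr, irmsd = ir,
               capri_class = capri_class(fnat, ir, lr),
               is_positive = binary_label(fnat, fnat_cutoff),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
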