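## Quality labeling: native contacts, f-nat, Kabsch superposition, ligand and
## interface RMSD, CAPRI classes and the binary near-native label.

test_that("native contacts follow the 5 angstrom heavy-atom rule", {
  ## two residues with closest heavy atoms at 4.9: included
  pdb <- c(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
           pdb_line(2, "CA", "ALA", "B", 1, 0, 0, 4.9, "C"))
  cs <- native_contacts(parse_complex(pdb, "A", "B"))
  expect_equal(nrow(cs), 1L)

  ## hydrogens at 3 angstrom but heavy atoms beyond 5: excluded
  pdb2 <- c(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
            pdb_line(2, "H", "ALA", "A", 1, 0, 0, 1.2, "H"),
            pdb_line(3, "CA", "ALA", "B", 1, 0, 0, 5.6, "C"),
            pdb_line(4, "H", "ALA", "B", 1, 0, 0, 4.2, "H"),
            pdb_line(5, "CB", "GLY", "B", 2, 0, 0, 4.0, "C"))
  cs2 <- native_contacts(parse_complex(pdb2, "A", "B"))
  expect_equal(cs2$ligand_res, "B|2|")

  ## no contacts at all: invalid reference
  expect_error(native_contacts(parse_complex(two_atom_pdb(50), "A", "B")),
               class = "grank_no_native_contacts_error")
})

test_that("contact sets match a brute-force residue-pair scan on random
           complexes", {
  set.seed(41)
  for (rep in 1:20) {
    cc <- random_cloud_complex(n_per = sample(4:10, 1L))
    got <- grank:::contact_pairs(cc, 5.0)
    ## exhaustive residue-pair scan over heavy atoms
    heavy <- cc$atoms[cc$atoms$element != "H", , drop = FALSE]
    expected <- character(0)
    arec <- heavy[heavy$chain_id == "A", , drop = FALSE]
    blig <- heavy[heavy$chain_id == "B", , drop = FALSE]
    for (i in seq_len(nrow(arec))) for (j in seq_len(nrow(blig))) {
      d <- sqrt(sum((unlist(arec[i, c("x", "y", "z")]) -
                       unlist(blig[j, c("x", "y", "z")]))^2))
      if (d <= 5.0)
        expected <- c(expected, paste(
          paste("A", arec$residue_seq[i], "", sep = "|"),
          paste("B", blig$residue_seq[j], "", sep = "|"), sep = "+"))
    }
    expect_setequal(paste(got$receptor_res, got$ligand_res, sep = "+"),
                    unique(expected))
  }
})

test_that("f-nat is 1 for the native, 0 for a destroyed interface, and
           fractional for partial interfaces", {
  nat <- make_native(decoy_recipe(seed = 42), "c")
  nset <- native_contacts(nat)
  expect_equal(compute_fnat(nat, nset), 1.0)

  far <- make_decoy(nat, 100, 0, seed = 1)
  expect_equal(compute_fnat(far, nset), 0.0)

  ## constructed toy: 4 native contacts, exactly 2 survive in the model
  mk <- function(zb) {
    pdb <- c(
      pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
      pdb_line(2, "CA", "ALA", "A", 2, 10, 0, 0, "C"),
      pdb_line(3, "CA", "ALA", "B", 1, 0, 0, zb[1L], "C"),
      pdb_line(4, "CA", "ALA", "B", 2, 10, 0, zb[2L], "C"),
      pdb_line(5, "CA", "ALA", "B", 3, 0, 3, zb[3L], "C"),
      pdb_line(6, "CA", "ALA", "B", 4, 10, 3, zb[4L], "C"))
    parse_complex(pdb, "A", "B")
  }
  nat2 <- mk(c(4, 4, 3.9, 3.9))    # residues A1-B1, A2-B2, A1-B3, A2-B4
  ns2 <- native_contacts(nat2)
  expect_equal(nrow(ns2), 4L)
  model2 <- mk(c(4, 4, 20, 20))    # B3, B4 moved away: 2 of 4 remain
  expect_equal(compute_fnat(model2, ns2), 0.5)
})

test_that("f-nat errors when a native-contact residue is missing from the
           model, and is invariant under joint rigid motion", {
  nat <- make_native(decoy_recipe(seed = 43), "c")
  nset <- native_contacts(nat)
  clipped <- nat
  clipped$atoms <- clipped$atoms[clipped$atoms$residue_seq != 10L |
                                   clipped$atoms$chain_id != "B", ,
                                 drop = FALSE]
  has10 <- "B|10|" %in% c(nset$ligand_res)
  if (has10)
    expect_error(compute_fnat(clipped, nset),
                 class = "grank_residue_mismatch_error")
  set.seed(44)
  for (rep in 1:5) {
    moved <- transform_complex(nat, random_rotation(), rnorm(3L, sd = 50))
    expect_equal(compute_fnat(moved, nset), 1.0)
  }
})

test_that("Kabsch superposition recovers exact transforms and the analytic
           two-point optimum", {
  set.seed(45)
  P <- matrix(rnorm(30L), ncol = 3L)
  id <- kabsch_superpose(P, P)
  expect_equal(id$rmsd, 0, tolerance = 1e-12)
  expect_equal(id$rotation, diag(3L), tolerance = 1e-9)

  for (rep in 1:20) {
    R <- random_rotation()
    t <- rnorm(3L, sd = 10)
    Q <- sweep(P %*% t(R), 2L, t, "+")
    fit <- kabsch_superpose(P, Q)
    expect_lt(fit$rmsd, 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }

  two <- kabsch_superpose(rbind(c(0, 0, 0), c(1, 0, 0)),
                          rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(two$rmsd, 0.5, tolerance = 1e-12)

  expect_error(kabsch_superpose(P, P[1:5, ]), class = "grank_shape_error")
})

test_that("Kabsch RMSD is optimal: never worse than identity alignment and
           matching a rotation grid search on toys", {
  set.seed(46)
  for (rep in 1:100) {
    n <- sample(3:12, 1L)
    P <- matrix(rnorm(n * 3L), ncol = 3L)
    Q <- P + matrix(rnorm(n * 3L, sd = 0.5), ncol = 3L)
    fit <- kabsch_superpose(P, Q)
    naive <- sqrt(mean(rowSums((P - Q)^2)))
    expect_lte(fit$rmsd, naive + 1e-12)
  }
  ## independent optimum: Euler-angle grid search refined by Nelder-Mead
  P <- matrix(c(0, 0, 0, 2, 0, 0, 0, 3, 0, 0, 0, 4), ncol = 3L, byrow = TRUE)
  Q <- P + matrix(rnorm(12L, sd = 0.4), ncol = 3L)
  fit <- kabsch_superpose(P, Q)
  Pc <- sweep(P, 2L, colMeans(P)); Qc <- sweep(Q, 2L, colMeans(Q))
  euler_rmsd <- function(ang) {
    Rz <- matrix(c(cos(ang[1L]), sin(ang[1L]), 0,
                   -sin(ang[1L]), cos(ang[1L]), 0, 0, 0, 1), 3L)
    Ry <- matrix(c(cos(ang[2L]), 0, -sin(ang[2L]), 0, 1, 0,
                   sin(ang[2L]), 0, cos(ang[2L])), 3L)
    Rx <- matrix(c(1, 0, 0, 0, cos(ang[3L]), sin(ang[3L]),
                   0, -sin(ang[3L]), cos(ang[3L])), 3L)
    sqrt(mean(rowSums((Pc - Qc %*% t(Rz %*% Ry %*% Rx))^2)))
  }
  grid <- seq(-pi, pi, length.out = 9L)
  best_ang <- NULL; best <- Inf
  for (a in grid) for (b in grid) for (cc in grid) {
    v <- euler_rmsd(c(a, b, cc))
    if (v < best) { best <- v; best_ang <- c(a, b, cc) }
  }
  ref <- stats::optim(best_ang, euler_rmsd,
                      control = list(reltol = 1e-14, maxit = 5000L))$value
  expect_equal(fit$rmsd, ref, tolerance = 1e-3)
  expect_lte(fit$rmsd, ref + 1e-9)
})

test_that("lRMSD is zero for rigid copies and equals the shift for
           pure-translation decoys", {
  nat <- make_native(decoy_recipe(seed = 47), "c")
  expect_equal(compute_lrmsd(nat, nat), 0, tolerance = 1e-9)
  moved <- transform_complex(nat, random_rotation(), c(5, -3, 8))
  expect_equal(compute_lrmsd(moved, nat), 0, tolerance = 1e-9)

  d <- make_decoy(nat, 3, 0, seed = 48)
  expect_equal(compute_lrmsd(d, nat), 3, tolerance = 1e-9)
  d2 <- make_decoy(nat, 7.25, 0, seed = 49)
  expect_equal(compute_lrmsd(d2, nat), 7.25, tolerance = 1e-9)
})

test_that("iRMSD is zero for rigid copies and matches a direct Kabsch
           computation for a single displaced interface residue", {
  nat <- make_native(decoy_recipe(seed = 50), "c")
  expect_equal(compute_irmsd(nat, nat), 0, tolerance = 1e-9)
  moved <- transform_complex(nat, random_rotation(), c(-4, 2, 6))
  expect_equal(compute_irmsd(moved, nat), 0, tolerance = 1e-9)

  ## displace one interface residue's backbone by 2 angstrom in the model
  cp <- grank:::contact_pairs(nat, 10.0)
  iface <- unique(c(cp$receptor_res, cp$ligand_res))
  rk <- paste(nat$atoms$chain_id, nat$atoms$residue_seq, nat$atoms$icode,
              sep = "|")
  target <- iface[1L]
  model <- nat
  sel <- rk == target & nat$atoms$atom_name %in% c("N", "CA", "C", "O")
  model$atoms$x[sel] <- model$atoms$x[sel] + 2
  got <- compute_irmsd(model, nat)
  bb <- nat$atoms$atom_name %in% c("N", "CA", "C", "O") & rk %in% iface
  Pn <- as.matrix(nat$atoms[bb, c("x", "y", "z")])
  Pm <- as.matrix(model$atoms[bb, c("x", "y", "z")])
  expect_equal(got, kabsch_superpose(Pn, Pm)$rmsd, tolerance = 1e-9)
  expect_gt(got, 0)
})

test_that("CAPRI classes follow the criteria table and improve monotonically", {
  expect_equal(capri_class(0.8, 0.5, 0.9), "high")
  expect_equal(capri_class(0.05, 0.2, 0.3), "incorrect")
  expect_equal(capri_class(0.35, 1.5, 4.0), "medium")
  expect_equal(capri_class(0.15, 3.5, 9.0), "acceptable")
  expect_equal(capri_class(0.45, 1.5, 4.5), "medium")

  ## monotonicity: improving one measure never demotes the class
  rank <- c(incorrect = 0L, acceptable = 1L, medium = 2L, high = 3L)
  set.seed(51)
  for (rep in 1:200) {
    fnat <- runif(1L); ir <- runif(1L, 0, 6); lr <- runif(1L, 0, 12)
    base <- rank[[capri_class(fnat, ir, lr)]]
    expect_gte(rank[[capri_class(min(fnat + 0.2, 1), ir, lr)]], base)
    expect_gte(rank[[capri_class(fnat, max(ir - 1, 0), lr)]], base)
    expect_gte(rank[[capri_class(fnat, ir, max(lr - 2, 0))]], base)
  }
})

test_that("the near-native label uses fnat >= 0.3 with an inclusive
           boundary", {
  expect_true(binary_label(0.5))
  expect_false(binary_label(0.1))
  expect_true(binary_label(0.3))
  expect_false(binary_label(0.2999999))
  expect_error(binary_label(1.2), class = "grank_range_error")
  expect_error(binary_label(-0.1), class = "grank_range_error")
})

test_that("label_models returns consistent per-model rows", {
  nat <- make_native(decoy_recipe(seed = 52), "cx")
  decs <- list(make_decoy(nat, 0, 0, seed = 1, model_id = "m1"),
               make_decoy(nat, 8, 15, seed = 2, model_id = "m2"))
  lab <- label_models(nat, decs)
  expect_equal(nrow(lab), 2L)
  expect_equal(lab$fnat[1L], 1.0)
  expect_true(lab$is_positive[1L])
  expect_equal(lab$capri_class[1L], "high")
  expect_lt(lab$fnat[2L], lab$fnat[1L])
  expect_identical(lab$is_positive, lab$fnat >= 0.3)
})
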