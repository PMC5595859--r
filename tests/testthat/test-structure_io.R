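test_that("parsing preserves atom count and resolves altlocs by occupancy", {
  lines <- c(
    sprintf("ATOM  %5d  N   ALA A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            1:10, 1:10, 1:10 * 1.0, rep(0, 10), rep(0, 10), rep(1, 10),
            rep(0, 10), rep("N", 10)),
    "HETATM   11  C1  LIG A 900      20.000   0.000   0.000  1.00  0.00           C",
    "HETATM   12  O1  LIG A 900      21.200   0.000   0.000  1.00  0.00           O",
    "END")
  m <- parse_structure(lines, id = "twelve")
  expect_equal(nrow(m$atoms), 12L)

  alt <- c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.40  0.00           C",
    "END")
  m <- parse_structure(alt)
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$x, 1.0)   # higher occupancy wins

  alt2 <- c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.30  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.70  0.00           C",
    "END")
  m <- parse_structure(alt2)
  expect_equal(m$atoms$x, 2.0)

  tie <- c(
    "ATOM      1  CA BALA A   1       2.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.50  0.00           C",
    "END")
  m <- parse_structure(tie)
  expect_equal(m$atoms$x, 1.0)   # occupancy tie goes to altloc A

  expect_error(parse_structure("/no/such/file.pdb"), "cannot read")
})

test_that("covalent bond inference matches the brute-force radius rule", {
  benz <- hexagon_atoms()
  bonds <- infer_bonds(benz)
  expect_equal(nrow(bonds), 6L)   # 6 C-C ring bonds at 1.39 A
  expect_equal(unname(bonds), unname(brute_bonds(benz)))

  set.seed(11)
  for (rep in 1:5) {
    n <- 25
    at <- make_atoms(paste0("X", 1:n),
                     sample(c("C", "N", "O", "S", "BR"), n, TRUE),
                     matrix(runif(3 * n, 0, 12), n, 3))
    expect_equal(unname(infer_bonds(at)), unname(brute_bonds(at)))
  }
})

test_that("grid neighbor search equals the O(n^2) scan", {
  set.seed(23)
  for (rep in 1:5) {
    xyz <- matrix(runif(3 * 60, 0, 20), 60, 3)
    cutoff <- runif(1, 2, 8)
    got <- neighbor_pairs(xyz, cutoff)
    got <- got[order(got[, 1], got[, 2]), 1:2, drop = FALSE]
    want <- brute_pairs(xyz, cutoff)
    want <- want[order(want[, 1], want[, 2]), , drop = FALSE]
    expect_equal(unname(got), unname(want))
  }
})

test_that("aromatic ring perception finds planar 5/6-rings only", {
  benz <- hexagon_atoms()
  rings <- perceive_aromatic_rings(benz, infer_bonds(benz))
  expect_length(rings, 1L)
  expect_equal(rings[[1]]$centroid, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(sqrt(sum(rings[[1]]$normal^2)), 1, tolerance = 1e-9)

  # cyclohexane chair (+-0.25 A puckering) fails the planarity tolerance
  chair <- hexagon_atoms()
  chair$z <- rep(c(0.25, -0.25), 3)
  expect_length(perceive_aromatic_rings(chair, infer_bonds(chair)), 0L)

  # naphthalene: two fused 6-rings sharing two atoms
  a <- 1.40
  pos <- rbind(
    c(0, a, 0), c(0.866 * a, a / 2, 0), c(0.866 * a, -a / 2, 0),
    c(0, -a, 0), c(-0.866 * a, -a / 2, 0), c(-0.866 * a, a / 2, 0),
    c(1.732 * a, a, 0), c(2.598 * a, a / 2, 0), c(2.598 * a, -a / 2, 0),
    c(1.732 * a, -a, 0))
  naph <- make_atoms(paste0("C", 1:10), rep("C", 10), pos)
  b <- infer_bonds(naph)
  # close the fused system explicitly (C2-C7, C3-C10 distances ~1.4 by
  # construction above)
  rings <- perceive_aromatic_rings(naph, b)
  expect_length(rings, 2L)
  shared <- intersect(rings[[1]]$member_serials, rings[[2]]$member_serials)
  expect_length(shared, 2L)
})

test_that("ring normal is canonical and independent of atom order", {
  set.seed(5)
  base <- hexagon_atoms()
  mo <- random_rigid_motion()
  rot <- base
  xyz <- sweep(as.matrix(base[, c("x", "y", "z")]) %*% t(mo$R), 2, mo$t, "+")
  rot$x <- xyz[, 1]; rot$y <- xyz[, 2]; rot$z <- xyz[, 3]
  r1 <- perceive_aromatic_rings(rot, infer_bonds(rot))[[1]]
  shuf <- rot[sample(1:6), ]
  r2 <- perceive_aromatic_rings(shuf, infer_bonds(shuf))[[1]]
  expect_equal(r1$normal, r2$normal, tolerance = 1e-9)
  expect_equal(sort(r1$member_serials), 1:6)
})

test_that("ligand selection excludes water and honors the allowlist", {
  at <- rbind(
    make_atoms("O", "O", matrix(c(0, 0, 0), 1), resname = "HOH",
               resno = 1L, chain = "A", het = TRUE),
    make_atoms(c("C1", "O1"), c("C", "O"),
               matrix(c(5, 0, 0, 6.2, 0, 0), 2, 3, byrow = TRUE),
               resname = "DRG", resno = 200L, chain = "A", het = TRUE),
    make_atoms(c("C1", "O1"), c("C", "O"),
               matrix(c(15, 0, 0, 16.2, 0, 0), 2, 3, byrow = TRUE),
               resname = "DRG", resno = 200L, chain = "B", het = TRUE))
  m <- make_model(at, id = "1abc")
  ligs <- select_ligands(m)
  expect_length(ligs, 2L)  # one per chain instance, water excluded

  allow <- data.frame(structure_id = "1abc", component_id = "DRG",
                      chain = "A", residue_number = 200L)
  expect_length(select_ligands(m, allowlist = allow), 1L)
  allow$component_id <- "XYZ"
  expect_length(select_ligands(m, allowlist = allow), 0L)
})

test_that("binding-site inclusion honors the cutoff exactly and matches brute force", {
  lig <- make_atoms("C1", "C", matrix(c(0, 0, 0), 1), het = TRUE)
  prot <- make_atoms(c("CA", "CB"), c("C", "C"),
                     matrix(c(7.4, 0, 0, 7.6, 0, 0), 2, 3, byrow = TRUE),
                     resname = "ALA", resno = 1L, chain = "A", het = FALSE)
  m <- make_model(rbind(lig, prot))
  sel <- select_ligands(m)[[1]]
  site <- build_binding_site(m, sel, cutoff = 7.5)
  expect_equal(site$protein_atoms$name, "CA")   # 7.4 in, 7.6 out

  set.seed(31)
  ligxyz <- matrix(runif(9, -2, 2), 3, 3)
  protxyz <- matrix(runif(90, -12, 12), 30, 3)
  at <- rbind(
    make_atoms(paste0("L", 1:3), rep("C", 3), ligxyz, het = TRUE),
    make_atoms(paste0("P", 1:30), rep("C", 30), protxyz,
               resname = "ALA", resno = 1:30, chain = "A", het = FALSE))
  m <- make_model(at)
  sel <- select_ligands(m)[[1]]
  site <- build_binding_site(m, sel, cutoff = 7.5)
  mind <- apply(protxyz, 1, function(p)
    min(sqrt(colSums((t(ligxyz) - p)^2))))
  expect_setequal(site$protein_atoms$serial, 3L + which(mind <= 7.5))

  bad <- sel
  bad$atom_serials <- c(bad$atom_serials, 999L)
  expect_error(build_binding_site(m, bad), "missing")
})

test_that("atom capability typing follows the heavy-atom rules", {
  # carbonyl O (1.23 A to C) -> acceptor only; hydroxyl O (1.43) -> both;
  # CH2 carbon between carbons -> hydrophobic; aromatic N -> acceptor;
  # Br on carbon -> halogen
  at <- rbind(
    make_atoms(c("C1", "O1", "C2", "C3", "C4", "O2", "BR1"),
               c("C", "O", "C", "C", "C", "O", "BR"),
               matrix(c(0, 0, 0,      # C1 carbonyl carbon
                        1.23, 0, 0,   # O1 carbonyl O
                        -1.5, 0, 0,   # C2 bonded C1, C3
                        -3.0, 0, 0,   # C3 bonded C2, C4
                        -4.5, 0, 0,   # C4 bonded C3, O2
                        -5.93, 0, 0,  # O2 hydroxyl
                        0, 1.9, 0),   # BR1 on C1
                      7, 3, byrow = TRUE), het = TRUE))
  m <- make_model(at)
  sel <- select_ligands(m)[[1]]
  site <- build_binding_site(m, sel)
  cl <- site$classes
  get <- function(nm) cl[match(at$serial[at$name == nm], cl$serial), ]
  expect_false(get("O1")$hbond_donor)
  expect_true(get("O1")$hbond_acceptor)
  expect_true(get("O2")$hbond_donor)
  expect_true(get("O2")$hbond_acceptor)
  expect_true(get("C3")$hydrophobic)     # bonded only to carbons
  expect_false(get("C1")$hydrophobic)    # bonded to O and Br
  expect_true(get("BR1")$halogen)

  ringN <- hexagon_atoms(prefix = "X", resname = "PYR")
  ringN$element[1] <- "N"
  ringN$name[1] <- "N1"
  m2 <- make_model(ringN)
  s2 <- build_binding_site(m2, select_ligands(m2)[[1]])
  n1 <- s2$classes[1, ]
  expect_true(n1$hbond_acceptor)
  expect_false(n1$hbond_donor)           # pyridine-like ring N
})

test_that("ring membership, classes and inclusion are rigid-motion invariant", {
  fx <- build_fixture(c("A", "B", "C", "E", "F", "H", "J"),
                      self_check = FALSE)
  m <- parse_structure(fx$pdb)
  sel <- select_ligands(m)[[1]]
  s0 <- build_binding_site(m, sel)
  set.seed(42)
  for (rep in 1:3) {
    mo <- random_rigid_motion()
    m2 <- transform_model(m, mo$R, mo$t)
    s2 <- build_binding_site(m2, sel)
    expect_identical(s2$protein_atoms$serial, s0$protein_atoms$serial)
    expect_identical(s2$classes, s0$classes)
    expect_identical(lapply(s2$ligand_rings, `[[`, "member_serials"),
                     lapply(s0$ligand_rings, `[[`, "member_serials"))
    expect_identical(lapply(s2$protein_rings, `[[`, "member_serials"),
                     lapply(s0$protein_rings, `[[`, "member_serials"))
  }
})
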