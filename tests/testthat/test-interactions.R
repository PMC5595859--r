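make_site <- function(atoms) {
  m <- make_model(atoms)
  sel <- select_ligands(m)[[1]]
  build_binding_site(m, sel)
}

test_that("hydrogen bonds respect distance and donor-angle criteria", {
  base <- function(o_x) rbind(
    make_atoms(c("N1", "H1"), c("N", "H"),
               matrix(c(0, 0, 0, 1.0, 0, 0), 2, 3, byrow = TRUE),
               het = TRUE),
    make_atoms(c("C", "O"), c("C", "O"),
               matrix(c(o_x + 1.23, 0, 0, o_x, 0, 0), 2, 3, byrow = TRUE),
               resname = "GLY", resno = 1L, chain = "A", het = FALSE))
  hb <- detect_hydrogen_bonds(make_site(base(2.9)))
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$da_distance, 2.9, tolerance = 1e-9)
  expect_true(hb$ligand_is_donor)

  expect_equal(nrow(detect_hydrogen_bonds(make_site(base(4.5)))), 0L)

  # bent geometry: acceptor at 90 degrees from the N-H direction is
  # rejected through the hydrogen-based angle criterion
  bent <- rbind(
    make_atoms(c("N1", "H1"), c("N", "H"),
               matrix(c(0, 0, 0, 1.0, 0, 0), 2, 3, byrow = TRUE),
               het = TRUE),
    make_atoms(c("C", "O"), c("C", "O"),
               matrix(c(1.0, 4.13, 0, 1.0, 2.9, 0), 2, 3, byrow = TRUE),
               resname = "GLY", resno = 1L, chain = "A", het = FALSE))
  expect_equal(nrow(detect_hydrogen_bonds(make_site(bent))), 0L)
})

test_that("hydrogen-bond enumeration equals the brute-force pair scan", {
  # three neighbor-less ligand oxygens (donor+acceptor) against two
  # protein carbonyl acceptors and one hydroxyl donor; no angular
  # restriction applies to neighbor-less donors
  set.seed(7)
  spaced_points <- function(n, lo, hi) {
    pts <- matrix(runif(3, lo, hi), 1, 3)
    while (nrow(pts) < n) {
      cand <- runif(3, lo, hi)
      if (min(sqrt(rowSums(sweep(pts, 2, cand)^2))) > 2.0)
        pts <- rbind(pts, cand)
    }
    pts
  }
  for (rep in 1:5) {
    all5 <- spaced_points(5, 0, 6)
    lxyz <- all5[1:3, , drop = FALSE]
    pxyz <- all5[4:5, , drop = FALSE]
    at <- rbind(
      make_atoms(paste0("O", 1:3), rep("O", 3), lxyz, het = TRUE),
      make_atoms(paste0("OW", 1:2), rep("O", 2), pxyz,
                 resname = "HOH2", resno = 1:2, chain = "A", het = FALSE))
    site <- make_site(at)
    hb <- detect_hydrogen_bonds(site)
    d <- as.matrix(dist(rbind(lxyz, pxyz)))[1:3, 4:5]
    want <- which(d <= 4.1, arr.ind = TRUE)
    got <- unique(hb[, c("ligand_anchor_serial", "protein_serial")])
    expect_equal(nrow(got), nrow(want))
    expect_setequal(paste(got$ligand_anchor_serial, got$protein_serial),
                    paste(want[, 1], want[, 2] + 3))
  }
})

test_that("hydrophobic contacts keep only the nearest partner per ligand atom", {
  at <- function(d1, d2) rbind(
    make_atoms(c("C1", "C2"), c("C", "C"),
               matrix(c(0, 0, 0, -1.5, 0, 0), 2, 3, byrow = TRUE),
               het = TRUE),
    make_atoms(c("CD1", "CD2"), c("C", "C"),
               matrix(c(d1, 0, 0, d2, 0.5, 0), 2, 3, byrow = TRUE),
               resname = "LEU", resno = 5L, chain = "A", het = FALSE))
  hp <- detect_hydrophobic_contacts(make_site(at(3.6, 20)))
  expect_equal(nrow(hp), 1L)
  expect_equal(hp$distance, 3.6, tolerance = 1e-9)

  expect_equal(nrow(detect_hydrophobic_contacts(make_site(at(4.2, 20)))), 0L)

  hp <- detect_hydrophobic_contacts(make_site(at(3.5, 3.8)))
  expect_equal(nrow(hp[hp$ligand_serial == 1, ]), 1L)
  expect_equal(min(hp$distance), 3.5, tolerance = 1e-9)
})

test_that("pi-stacking classifies parallel and opposite-face geometries", {
  two <- rbind(
    hexagon_atoms(het = TRUE),
    hexagon_atoms(center = c(0, 0, 3.5), prefix = "P", resname = "PHE",
                  resno = 1L, chain = "A", het = FALSE))
  st <- detect_pi_stacking(make_site(two))
  expect_equal(nrow(st), 1L)
  expect_equal(st$stack_type, "parallel")
  expect_equal(st$centroid_distance, 3.5, tolerance = 1e-9)
  expect_equal(st$lateral_offset, 0, tolerance = 1e-9)

  far <- rbind(
    hexagon_atoms(het = TRUE),
    hexagon_atoms(center = c(0, 0, 8), prefix = "P", resname = "PHE",
                  resno = 1L, chain = "A", het = FALSE))
  expect_equal(nrow(detect_pi_stacking(make_site(far))), 0L)

  sandwich <- rbind(
    hexagon_atoms(het = TRUE),
    hexagon_atoms(center = c(0, 0, 3.5), prefix = "P", resname = "PHE",
                  resno = 1L, chain = "A", het = FALSE),
    hexagon_atoms(center = c(0, 0, -3.5), prefix = "Q", resname = "PHE",
                  resno = 2L, chain = "A", het = FALSE))
  st <- detect_pi_stacking(make_site(sandwich))
  expect_equal(nrow(st), 2L)
  expect_setequal(st$face_sign, c(1L, -1L))
})

test_that("halogen bonds require Cl/Br/I and both angle windows", {
  geom <- function(elem, donor_deg) {
    xdir <- c(-1, 0, 0)
    adir <- c(cos((180 - donor_deg) * pi / 180),
              sin((180 - donor_deg) * pi / 180), 0)
    A <- c(1.9, 0, 0) + 3.3 * adir
    # acceptor neighbor Y at 120 degrees from the A->X direction
    negA <- -adir
    Ydir <- c(cos(2 * pi / 3) * negA[1] - sin(2 * pi / 3) * negA[2],
              sin(2 * pi / 3) * negA[1] + cos(2 * pi / 3) * negA[2], 0)
    Y <- A + 1.23 * Ydir
    rbind(
      make_atoms(c("C1", "X1"), c("C", elem),
                 matrix(c(0, 0, 0, 1.9, 0, 0), 2, 3, byrow = TRUE),
                 het = TRUE),
      make_atoms(c("C", "O"), c("C", "O"),
                 matrix(c(Y, A), 2, 3, byrow = TRUE),
                 resname = "GLY", resno = 1L, chain = "A", het = FALSE))
  }
  xb <- detect_halogen_bonds(make_site(geom("BR", 170)))
  expect_equal(nrow(xb), 1L)
  expect_equal(xb$distance, 3.3, tolerance = 1e-9)
  expect_equal(xb$donor_angle, 170, tolerance = 1e-6)

  expect_equal(nrow(detect_halogen_bonds(make_site(geom("F", 170)))), 0L)
  expect_equal(nrow(detect_halogen_bonds(make_site(geom("BR", 120)))), 0L)
})

test_that("profiles are deterministic and empty without protein atoms", {
  lone <- hexagon_atoms(het = TRUE)
  m <- make_model(lone)
  site <- build_binding_site(m, select_ligands(m)[[1]])
  prof <- profile_complex(site)
  expect_equal(nrow(prof$hbonds), 0L)
  expect_equal(nrow(prof$hydrophobic), 0L)
  expect_equal(nrow(prof$pistacks), 0L)
  expect_equal(nrow(prof$halogen_bonds), 0L)

  fx <- build_fixture(c("A", "E", "H", "J"), self_check = FALSE)
  mm <- parse_structure(fx$pdb)
  s <- build_binding_site(mm, select_ligands(mm)[[1]])
  p1 <- profile_complex(s)
  p2 <- profile_complex(s)
  for (f in c("hbonds", "hydrophobic", "pistacks", "halogen_bonds"))
    expect_identical(p1[[f]], p2[[f]])
})

test_that("enlarging distance thresholds never removes a detection", {
  fx <- build_fixture(c("A", "B", "C", "E", "F", "G", "H", "I", "J"),
                      self_check = FALSE)
  m <- parse_structure(fx$pdb)
  site <- build_binding_site(m, select_ligands(m)[[1]])
  tight <- profile_complex(site, interaction_config())
  loose <- profile_complex(site, interaction_config(
    hbond_max_dist = 5.0, hydrophobic_max_dist = 5.0,
    stack_max_dist = 6.5, halogen_max_dist = 5.0))
  keyify <- function(df, cols) do.call(paste, df[cols])
  expect_true(all(keyify(tight$hbonds,
                         c("donor_serial", "acceptor_serial")) %in%
                  keyify(loose$hbonds,
                         c("donor_serial", "acceptor_serial"))))
  expect_true(all(keyify(tight$pistacks,
                         c("ligand_ring", "protein_ring")) %in%
                  keyify(loose$pistacks,
                         c("ligand_ring", "protein_ring"))))
  expect_true(all(keyify(tight$halogen_bonds,
                         c("halogen_serial", "acceptor_serial")) %in%
                  keyify(loose$halogen_bonds,
                         c("halogen_serial", "acceptor_serial"))))
  expect_gte(nrow(loose$hbonds), nrow(tight$hbonds))
})

test_that("interaction geometry is rigid-motion invariant", {
  fx <- build_fixture(c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J")[
    c(1, 2, 3, 5, 8, 10)], self_check = FALSE)  # {A,B,C,E,H,J}
  m <- parse_structure(fx$pdb)
  sel <- select_ligands(m)[[1]]
  p0 <- profile_complex(build_binding_site(m, sel))
  set.seed(99)
  for (rep in 1:3) {
    mo <- random_rigid_motion()
    p1 <- profile_complex(build_binding_site(transform_model(m, mo$R, mo$t),
                                             sel))
    expect_equal(p1$hbonds$da_distance, p0$hbonds$da_distance,
                 tolerance = 1e-6)
    expect_equal(p1$hbonds$donor_angle, p0$hbonds$donor_angle,
                 tolerance = 1e-6)
    expect_identical(p1$hbonds$donor_serial, p0$hbonds$donor_serial)
    expect_equal(p1$hydrophobic$distance, p0$hydrophobic$distance,
                 tolerance = 1e-6)
    expect_equal(p1$pistacks$centroid_distance,
                 p0$pistacks$centroid_distance, tolerance = 1e-6)
    expect_equal(p1$pistacks$planar_angle, p0$pistacks$planar_angle,
                 tolerance = 1e-4)
    expect_identical(p1$pistacks$stack_type, p0$pistacks$stack_type)
    # face signs are defined against the canonicalized ring normal and
    # may flip globally per ring under rotation; opposition is invariant
    rel <- function(p) {
      s <- split(p$pistacks$face_sign, p$pistacks$ligand_ring)
      lapply(s, function(v) v * v[1])
    }
    expect_identical(rel(p1), rel(p0))
    expect_equal(p1$halogen_bonds$donor_angle, p0$halogen_bonds$donor_angle,
                 tolerance = 1e-4)
  }
})
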