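# In-code fixtures and independent brute-force oracles used across the
# suite. Oracles are deliberately naive (plain loops) and share no code
# with the implementation paths they check.

make_atoms <- function(name, element, xyz, resname = "LIG", resno = 900L,
                       chain = "L", het = TRUE) {
  n <- length(name)
  data.frame(serial = seq_len(n), name = name, element = element,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             resname = rep_len(resname, n), resno = rep_len(resno, n),
             chain = rep_len(chain, n), het = rep_len(het, n),
             altloc = "", stringsAsFactors = FALSE)
}

make_model <- function(atoms, id = "test", bonds = NULL) {
  atoms$serial <- seq_len(nrow(atoms))
  if (is.null(bonds)) bonds <- infer_bonds(atoms)
  structure(list(id = id, atoms = atoms, bonds = bonds),
            class = "ip_structure")
}

# regular planar hexagon of carbons (benzene-like), radius 1.39
hexagon_atoms <- function(center = c(0, 0, 0), normal_z = TRUE,
                          prefix = "C", element = "C", resname = "BNZ",
                          resno = 900L, chain = "L", het = TRUE) {
  ang <- seq(0, 300, by = 60) * pi / 180
  xyz <- t(sapply(ang, function(a)
    center + 1.39 * c(cos(a), sin(a), 0)))
  make_atoms(paste0(prefix, 1:6), rep(element, 6), xyz,
             resname = resname, resno = resno, chain = chain, het = het)
}

# brute-force O(n^2) covalent bond oracle (radius sum + slack)
brute_bonds <- function(atoms, slack = 0.45) {
  radii <- c("H" = 0.31, "C" = 0.76, "N" = 0.71, "O" = 0.66, "S" = 1.05,
             "BR" = 1.20, "CL" = 1.02, "I" = 1.39, "P" = 1.07, "F" = 0.57)
  out <- NULL
  n <- nrow(atoms)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((atoms[i, c("x", "y", "z")] -
                     atoms[j, c("x", "y", "z")])^2))
      r <- radii[atoms$element[i]] + radii[atoms$element[j]] + slack
      if (!is.na(r) && d <= r && d > 0.4)
        out <- rbind(out, c(atoms$serial[i], atoms$serial[j]))
    }
  }
  if (is.null(out)) return(matrix(integer(0), 0, 2))
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# brute-force neighbor pairs within cutoff
brute_pairs <- function(xyz, cutoff) {
  out <- NULL
  n <- nrow(xyz)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d <= cutoff) out <- rbind(out, c(i, j))
    }
  }
  out
}

# naive average-linkage agglomeration; returns the cophenetic matrix
naive_average_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(NA, NA); besth <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        h <- mean(d[clusters[[a]], clusters[[b]]])
        if (h < besth) { besth <- h; best <- c(a, b) }
      }
    }
    ca <- clusters[[best[1]]]; cb <- clusters[[best[2]]]
    for (i in ca) for (j in cb) coph[i, j] <- coph[j, i] <- besth
    clusters[[best[1]]] <- c(ca, cb)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# random evaluation context for the pattern fuzz tests
random_context <- function() {
  nst <- sample(0:3, 1)
  stacks <- if (nst > 0)
    data.frame(ligand_ring = 1L, protein_ring = sample(1:3, nst),
               centroid_distance = runif(nst, 3, 5.5),
               planar_angle = runif(nst, 0, 30),
               lateral_offset = runif(nst, 0, 2),
               stack_type = sample(c("parallel", "tshaped"), nst, TRUE),
               face_sign = sample(c(-1L, 0L, 1L), nst, TRUE),
               protein_residue = paste0("P:HIS", sample(1:3, nst)))
  else
    data.frame(ligand_ring = integer(0), protein_ring = integer(0),
               centroid_distance = numeric(0), planar_angle = numeric(0),
               lateral_offset = numeric(0), stack_type = character(0),
               face_sign = integer(0), protein_residue = character(0))
  nhb <- sample(0:3, 1)
  mh <- if (nhb > 0)
    data.frame(donor_serial = sample(100:200, nhb),
               acceptor_serial = sample(300:400, nhb),
               ligand_is_donor = sample(c(TRUE, FALSE), nhb, TRUE),
               da_distance = runif(nhb, 2.5, 4),
               donor_angle = runif(nhb, 100, 180),
               ligand_anchor_serial = sample(1:20, nhb),
               protein_serial = sample(300:400, nhb),
               protein_residue = paste0("P:GLN", sample(1:2, nhb, TRUE)))
  else
    data.frame(donor_serial = integer(0), acceptor_serial = integer(0),
               ligand_is_donor = logical(0), da_distance = numeric(0),
               donor_angle = numeric(0), ligand_anchor_serial = integer(0),
               protein_serial = integer(0), protein_residue = character(0))
  dirs <- if (nhb > 0) matrix(rnorm(nhb * 3), nhb, 3) else
    matrix(numeric(0), 0, 3)
  structure(list(
    ring_index = 1L,
    ring = list(member_serials = 1:6, centroid = c(0, 0, 0),
                normal = c(0, 0, 1)),
    stacks = stacks,
    moiety_hbonds = mh,
    moiety_hbond_dirs = dirs,
    hbond_x = runif(sample(0:3, 1), 0, 10),
    hydrophobic_x = runif(sample(0:3, 1), 0, 10),
    halogen_x = runif(sample(0:3, 1), 0, 12)
  ), class = "ip_ring_context")
}

check_implications <- function(flags) {
  imp <- pattern_implications()
  all(vapply(names(imp), function(p)
    !flags[[p]] || flags[[imp[[p]]]], logical(1)))
}

# apply a rigid motion to every atom of a structure model
transform_model <- function(model, R, t) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz2 <- sweep(xyz %*% t(R), 2, t, "+")
  model$atoms$x <- xyz2[, 1]
  model$atoms$y <- xyz2[, 2]
  model$atoms$z <- xyz2[, 3]
  model
}

random_rigid_motion <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qd <- qr(m)
  R <- qr.Q(qd) %*% diag(sign(diag(qr.R(qd))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 5))
}
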