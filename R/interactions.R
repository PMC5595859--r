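## Detection of the four noncovalent interaction types used by the
## BVDU patterns: hydrogen bonds, hydrophobic contacts, pi-stacking and
## halogen bonds. Geometric thresholds default to the documented
## standard settings of the reference interaction profiler and are all
## overridable through the detection config.

#' Detection configuration
#'
#' Geometric thresholds for the four interaction detectors. Distances
#' in Angstrom, angles in degrees; all cuts are inclusive.
#'
#' @param hbond_max_dist maximal donor-acceptor distance (4.1).
#' @param hbond_min_angle minimal donor angle when computed through an
#'   explicit hydrogen (100).
#' @param hbond_surrogate_min_angle minimal heavy-atom surrogate donor
#'   angle (neighbor-donor-acceptor) when hydrogens are absent (90).
#' @param hydrophobic_max_dist maximal carbon-carbon distance (4.0).
#' @param stack_max_dist maximal ring centroid-centroid distance (5.5).
#' @param stack_max_offset maximal lateral ring offset (2.0).
#' @param stack_parallel_max_angle planar angle upper bound for parallel
#'   stacks (30).
#' @param stack_tshape_min_angle planar angle lower bound for T-shaped
#'   stacks (60; upper bound is 90 by construction).
#' @param halogen_max_dist maximal halogen-acceptor distance (4.0).
#' @param halogen_donor_angle,halogen_donor_tol C-X...A angle window
#'   center and half-width (165 +/- 30).
#' @param halogen_acceptor_angle,halogen_acceptor_tol Y-A...X angle
#'   window center and half-width (120 +/- 30).
#' @param include_fluorine treat F as halogen-bond donor (FALSE).
#' @return list of class \code{ip_config}.
#' @export
interaction_config <- function(hbond_max_dist = 4.1,
                               hbond_min_angle = 100,
                               hbond_surrogate_min_angle = 90,
                               hydrophobic_max_dist = 4.0,
                               stack_max_dist = 5.5,
                               stack_max_offset = 2.0,
                               stack_parallel_max_angle = 30,
                               stack_tshape_min_angle = 60,
                               halogen_max_dist = 4.0,
                               halogen_donor_angle = 165,
                               halogen_donor_tol = 30,
                               halogen_acceptor_angle = 120,
                               halogen_acceptor_tol = 30,
                               include_fluorine = FALSE) {
  cfg <- as.list(environment())
  stopifnot(all(vapply(cfg[!names(cfg) %in% "include_fluorine"],
                       function(v) is.numeric(v) && v > 0, logical(1))))
  structure(cfg, class = "ip_config")
}

.coords <- function(atoms, serials) {
  idx <- match(serials, atoms$serial)
  as.matrix(atoms[idx, c("x", "y", "z")])
}

.class_serials <- function(site, side, what) {
  pool <- if (side == "ligand") site$ligand_atoms$serial else
    site$protein_atoms$serial
  cl <- site$classes
  cl$serial[cl$serial %in% pool & cl[[what]]]
}

## Hydrogens bonded to a given atom (serials), from the full model.
.bonded_h <- function(site, serial) {
  b <- site$bonds
  nbs <- c(b[b[, 1] == serial, 2], b[b[, 2] == serial, 1])
  at <- site$model_atoms
  nbs[at$element[match(nbs, at$serial)] == "H"]
}

.heavy_neighbors <- function(site, serial) {
  b <- site$bonds
  nbs <- c(b[b[, 1] == serial, 2], b[b[, 2] == serial, 1])
  at <- site$model_atoms
  nbs[at$element[match(nbs, at$serial)] != "H"]
}

.model_xyz <- function(site, serial) {
  at <- site$model_atoms
  as.numeric(at[match(serial, at$serial), c("x", "y", "z")])
}

## Donor angle for a candidate donor-acceptor pair. With explicit
## hydrogens the angle is measured at the hydrogen (D-H...A, best H);
## without, the heavy-atom surrogate is the largest
## neighbor-donor-acceptor angle. A donor without any neighbor (e.g. a
## free water oxygen) imposes no angular restriction.
.donor_angle <- function(site, donor, acceptor) {
  dpos <- .model_xyz(site, donor)
  apos <- .model_xyz(site, acceptor)
  hs <- .bonded_h(site, donor)
  if (length(hs) > 0L) {
    ang <- vapply(hs, function(h) angle3(dpos, .model_xyz(site, h), apos),
                  numeric(1))
    return(list(angle = max(ang), basis = "hydrogen"))
  }
  heavies <- .heavy_neighbors(site, donor)
  if (length(heavies) == 0L)
    return(list(angle = 180, basis = "none"))
  ang <- vapply(heavies, function(y) angle3(.model_xyz(site, y), dpos, apos),
                numeric(1))
  list(angle = max(ang), basis = "surrogate")
}

#' Detect hydrogen bonds across the ligand-protein interface
#'
#' All donor/acceptor pairs (both directions) with donor-acceptor
#' distance within \code{hbond_max_dist} and an admissible donor angle:
#' measured through an explicit hydrogen when present (minimum
#' \code{hbond_min_angle}), otherwise through the heavy-atom
#' neighbor-donor-acceptor surrogate (minimum
#' \code{hbond_surrogate_min_angle}). Pairs detectable in both
#' directions are collapsed to the better-angle direction.
#'
#' @param site an \code{ip_site}.
#' @param config an \code{\link{interaction_config}}.
#' @return data frame with columns donor_serial, acceptor_serial,
#'   ligand_is_donor, da_distance, donor_angle, ligand_anchor_serial,
#'   protein_serial, protein_residue; ordered by ligand anchor then
#'   protein serial.
#' @export
detect_hydrogen_bonds <- function(site, config = interaction_config()) {
  empty <- data.frame(donor_serial = integer(0), acceptor_serial = integer(0),
                      ligand_is_donor = logical(0), da_distance = numeric(0),
                      donor_angle = numeric(0),
                      ligand_anchor_serial = integer(0),
                      protein_serial = integer(0),
                      protein_residue = character(0))
  cand <- rbind(
    expand.grid(donor = .class_serials(site, "ligand", "hbond_donor"),
                acceptor = .class_serials(site, "protein", "hbond_acceptor"),
                lig_donor = TRUE),
    expand.grid(donor = .class_serials(site, "protein", "hbond_donor"),
                acceptor = .class_serials(site, "ligand", "hbond_acceptor"),
                lig_donor = FALSE))
  if (nrow(cand) == 0L) return(empty)
  dpos <- .coords(site$atoms, cand$donor)
  apos <- .coords(site$atoms, cand$acceptor)
  cand$dist <- sqrt(rowSums((dpos - apos)^2))
  cand <- cand[cand$dist <= config$hbond_max_dist, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    da <- .donor_angle(site, cand$donor[k], cand$acceptor[k])
    minang <- if (da$basis == "hydrogen") config$hbond_min_angle else
      config$hbond_surrogate_min_angle
    if (da$angle < minang) next
    rows[[length(rows) + 1L]] <- data.frame(
      donor_serial = cand$donor[k], acceptor_serial = cand$acceptor[k],
      ligand_is_donor = cand$lig_donor[k], da_distance = cand$dist[k],
      donor_angle = da$angle,
      ligand_anchor_serial = if (cand$lig_donor[k]) cand$donor[k] else
        cand$acceptor[k],
      protein_serial = if (cand$lig_donor[k]) cand$acceptor[k] else
        cand$donor[k])
  }
  if (length(rows) == 0L) return(empty)
  hb <- do.call(rbind, rows)
  # collapse the two directions of the same (unordered) atom pair
  pair <- paste(pmin(hb$donor_serial, hb$acceptor_serial),
                pmax(hb$donor_serial, hb$acceptor_serial))
  keep <- unlist(lapply(split(seq_len(nrow(hb)), pair), function(idx) {
    idx[which.max(hb$donor_angle[idx])]
  }))
  hb <- hb[keep, , drop = FALSE]
  at <- site$atoms
  pidx <- match(hb$protein_serial, at$serial)
  hb$protein_residue <- paste0(at$chain[pidx], ":", at$resname[pidx],
                               at$resno[pidx])
  hb <- hb[order(hb$ligand_anchor_serial, hb$protein_serial), , drop = FALSE]
  rownames(hb) <- NULL
  hb
}

#' Detect hydrophobic contacts
#'
#' Ligand x protein pairs of hydrophobic carbons within
#' \code{hydrophobic_max_dist}; per ligand atom only the nearest protein
#' partner is kept, which avoids inflating contact counts in packed
#' apolar pockets.
#'
#' @inheritParams detect_hydrogen_bonds
#' @return data frame with columns ligand_serial, protein_serial,
#'   distance; ordered by ligand serial.
#' @export
detect_hydrophobic_contacts <- function(site, config = interaction_config()) {
  empty <- data.frame(ligand_serial = integer(0), protein_serial = integer(0),
                      distance = numeric(0))
  lig <- .class_serials(site, "ligand", "hydrophobic")
  pro <- .class_serials(site, "protein", "hydrophobic")
  if (length(lig) == 0L || length(pro) == 0L) return(empty)
  d <- cross_dist(.coords(site$atoms, lig), .coords(site$atoms, pro))
  rows <- list()
  for (i in seq_along(lig)) {
    j <- which.min(d[i, ])
    if (d[i, j] <= config$hydrophobic_max_dist)
      rows[[length(rows) + 1L]] <- data.frame(
        ligand_serial = lig[i], protein_serial = pro[j], distance = d[i, j])
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$ligand_serial, out$protein_serial), , drop = FALSE]
}

#' Detect pi-stacking between ligand and protein aromatic rings
#'
#' Ring pairs with centroid distance within \code{stack_max_dist} and
#' lateral offset within \code{stack_max_offset}; the planar angle
#' (between ring normals, folded into [0, 90]) classifies the stack as
#' parallel (<= \code{stack_parallel_max_angle}) or T-shaped
#' (>= \code{stack_tshape_min_angle}). \code{face_sign} is the side of
#' the ligand-ring plane holding the protein-ring centroid: the sign of
#' (protein centroid - ligand centroid) dot (ligand normal); exactly
#' in-plane centroids get sign 0.
#'
#' @inheritParams detect_hydrogen_bonds
#' @return data frame with columns ligand_ring, protein_ring (indices
#'   into the site's ring lists), centroid_distance, planar_angle,
#'   lateral_offset, stack_type, face_sign, protein_residue.
#' @export
detect_pi_stacking <- function(site, config = interaction_config()) {
  empty <- data.frame(ligand_ring = integer(0), protein_ring = integer(0),
                      centroid_distance = numeric(0), planar_angle = numeric(0),
                      lateral_offset = numeric(0), stack_type = character(0),
                      face_sign = integer(0), protein_residue = character(0))
  if (length(site$ligand_rings) == 0L || length(site$protein_rings) == 0L)
    return(empty)
  rows <- list()
  for (i in seq_along(site$ligand_rings)) {
    lr <- site$ligand_rings[[i]]
    for (j in seq_along(site$protein_rings)) {
      pr <- site$protein_rings[[j]]
      v <- pr$centroid - lr$centroid
      d <- vnorm(v)
      if (d > config$stack_max_dist) next
      ang <- vec_angle(lr$normal, pr$normal)
      if (ang > 90) ang <- 180 - ang
      off1 <- vnorm(v - sum(v * lr$normal) * lr$normal)
      off2 <- vnorm(-v - sum(-v * pr$normal) * pr$normal)
      offset <- min(off1, off2)
      if (offset > config$stack_max_offset) next
      type <- if (ang <= config$stack_parallel_max_angle) "parallel"
      else if (ang >= config$stack_tshape_min_angle) "tshaped"
      else next
      dot <- sum(v * lr$normal)
      fs <- if (abs(dot) < 1e-9) 0L else as.integer(sign(dot))
      rows[[length(rows) + 1L]] <- data.frame(
        ligand_ring = i, protein_ring = j, centroid_distance = d,
        planar_angle = ang, lateral_offset = offset, stack_type = type,
        face_sign = fs, protein_residue = pr$residue)
    }
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Detect halogen bonds
#'
#' Ligand halogen (Cl, Br, I; optionally F) against protein acceptors
#' (O, N with lone pair, or sulfur with at most two neighbors), with
#' distance within \code{halogen_max_dist}, donor angle C-X...A inside
#' \code{halogen_donor_angle +/- halogen_donor_tol} and acceptor angle
#' Y-A...X inside \code{halogen_acceptor_angle +/- halogen_acceptor_tol}
#' for some neighbor Y of the acceptor (an acceptor without neighbors
#' imposes no acceptor-angle restriction).
#'
#' @inheritParams detect_hydrogen_bonds
#' @return data frame with columns halogen_serial, acceptor_serial,
#'   distance, donor_angle, acceptor_angle, protein_residue.
#' @export
detect_halogen_bonds <- function(site, config = interaction_config()) {
  empty <- data.frame(halogen_serial = integer(0), acceptor_serial = integer(0),
                      distance = numeric(0), donor_angle = numeric(0),
                      acceptor_angle = numeric(0), protein_residue = character(0))
  hal <- .class_serials(site, "ligand", "halogen")
  pro <- site$protein_atoms
  acc <- .class_serials(site, "protein", "hbond_acceptor")
  sulfur <- pro$serial[pro$element == "S"]
  sulfur <- sulfur[vapply(sulfur, function(s)
    length(.heavy_neighbors(site, s)) <= 2L, logical(1))]
  acc <- sort(unique(c(acc, sulfur)))
  acc <- acc[pro$element[match(acc, pro$serial)] %in% c("O", "N", "S")]
  if (length(hal) == 0L || length(acc) == 0L) return(empty)
  rows <- list()
  for (x in hal) {
    xpos <- .model_xyz(site, x)
    cx <- .heavy_neighbors(site, x)
    if (length(cx) == 0L) next  # halide ion, no sigma hole direction
    cpos <- .model_xyz(site, cx[1L])
    for (a in acc) {
      apos <- .model_xyz(site, a)
      d <- vnorm(apos - xpos)
      if (d > config$halogen_max_dist) next
      dang <- angle3(cpos, xpos, apos)
      if (abs(dang - config$halogen_donor_angle) > config$halogen_donor_tol)
        next
      ys <- .heavy_neighbors(site, a)
      if (length(ys) == 0L) {
        aang <- NA_real_
      } else {
        angs <- vapply(ys, function(y) angle3(.model_xyz(site, y), apos, xpos),
                       numeric(1))
        ok <- abs(angs - config$halogen_acceptor_angle) <=
          config$halogen_acceptor_tol
        if (!any(ok)) next
        aang <- angs[ok][1L]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        halogen_serial = x, acceptor_serial = a, distance = d,
        donor_angle = dang, acceptor_angle = aang)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  at <- site$atoms
  pidx <- match(out$acceptor_serial, at$serial)
  out$protein_residue <- paste0(at$chain[pidx], ":", at$resname[pidx],
                                at$resno[pidx])
  out <- out[order(out$halogen_serial, out$acceptor_serial), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Profile a binding-site complex
#'
#' Runs all four interaction detectors and bundles the results with a
#' snapshot of the detection configuration.
#'
#' @inheritParams detect_hydrogen_bonds
#' @return An object of class \code{ip_profile}: list with
#'   \code{structure_id}, \code{ligand_id}, the four interaction tables
#'   (\code{hbonds}, \code{hydrophobic}, \code{pistacks},
#'   \code{halogen_bonds}), the \code{site} and the \code{config}.
#' @export
profile_complex <- function(site, config = interaction_config()) {
  structure(list(
    structure_id = site$structure_id,
    ligand_id = site$ligand$component_id,
    hbonds = detect_hydrogen_bonds(site, config),
    hydrophobic = detect_hydrophobic_contacts(site, config),
    pistacks = detect_pi_stacking(site, config),
    halogen_bonds = detect_halogen_bonds(site, config),
    site = site,
    config = config
  ), class = "ip_profile")
}

#' Serialize an interaction profile to JSON
#'
#' @param profile an \code{ip_profile}.
#' @param path optional output path; when \code{NULL} the JSON string is
#'   returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
profile_to_json <- function(profile, path = NULL) {
  obj <- list(
    structure_id = profile$structure_id,
    ligand_id = profile$ligand_id,
    hydrogen_bonds = profile$hbonds,
    hydrophobic_contacts = profile$hydrophobic,
    pi_stacks = profile$pistacks,
    halogen_bonds = profile$halogen_bonds,
    config = unclass(profile$config)
  )
  js <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
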