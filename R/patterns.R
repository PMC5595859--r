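## Evaluation of the ten BVDU interaction patterns A-J on an interaction
## profile. All patterns are defined relative to one ligand aromatic
## ring that is engaged in pi-stacking (the "base ring", pattern A);
## distal distances x are measured from the ligand-side interaction
## anchor to the base-ring centroid, and the distal bands are strict
## inequalities.

.PATTERNS <- LETTERS[1:10]

.IMPLICATIONS <- list(
  B = "A", C = "B", D = "B", E = "A", F = "E", G = "E",
  H = "A", I = "A", J = "A"
)

#' Pattern configuration
#'
#' Numeric constants of the BVDU pattern definitions: the parallel
#' hydrogen-bond angle window (pattern G) and the three distal distance
#' bands (patterns H, I, J), all strict.
#'
#' @param parallel_hbond_angle_center,parallel_hbond_tolerance pattern G
#'   qualifies when the angle between the directed donor-to-acceptor
#'   vectors of two base-ring hydrogen bonds lies within
#'   center +/- tolerance (default 180 +/- 18 degrees).
#' @param distal_hydrophobic_band,distal_hbond_band,distal_halogen_band
#'   open intervals (Angstrom) for the anchor-to-ring-centroid distance
#'   of patterns H (4.0, 6.5), I (5.4, 6.1) and J (7.8, 9.2).
#' @return list of class \code{ip_pattern_config}.
#' @export
pattern_config <- function(parallel_hbond_angle_center = 180,
                           parallel_hbond_tolerance = 18,
                           distal_hydrophobic_band = c(4.0, 6.5),
                           distal_hbond_band = c(5.4, 6.1),
                           distal_halogen_band = c(7.8, 9.2)) {
  for (b in list(distal_hydrophobic_band, distal_hbond_band,
                 distal_halogen_band))
    if (length(b) != 2L || b[1] >= b[2])
      stop("distal bands must be (lower, upper) with lower < upper")
  if (parallel_hbond_tolerance <= 0 || parallel_hbond_tolerance >= 90)
    stop("parallel_hbond_tolerance must be in (0, 90)")
  structure(list(parallel_hbond_angle_center = parallel_hbond_angle_center,
                 parallel_hbond_tolerance = parallel_hbond_tolerance,
                 distal_hydrophobic_band = distal_hydrophobic_band,
                 distal_hbond_band = distal_hbond_band,
                 distal_halogen_band = distal_halogen_band),
            class = "ip_pattern_config")
}

#' Pattern implication table
#'
#' The definitional implications among the patterns: B, E, H, I, J each
#' require the base pattern A; C and D require B; F and G require E.
#'
#' @return named list mapping each pattern to its direct prerequisite.
#' @export
pattern_implications <- function() .IMPLICATIONS

#' Is a pattern set closed under the implications?
#'
#' @param set character vector of pattern letters.
#' @return \code{TRUE}, or the name of the first violated prerequisite
#'   as an attribute of \code{FALSE}.
#' @export
is_closed_pattern_set <- function(set) {
  for (p in intersect(names(.IMPLICATIONS), set)) {
    req <- .IMPLICATIONS[[p]]
    if (!req %in% set) {
      out <- FALSE
      attr(out, "violation") <- paste0(p, " requires ", req)
      return(out)
    }
  }
  TRUE
}

#' Enumerate all implication-closed pattern subsets
#'
#' @return list of character vectors (including the empty set); 201
#'   subsets in total.
#' @export
closed_pattern_sets <- function() {
  sets <- list(character(0))
  stack_opts <- list(character(0), "B", c("B", "C"), c("B", "D"),
                     c("B", "C", "D"))
  hb_opts <- list(character(0), "E", c("E", "F"), c("E", "G"),
                  c("E", "F", "G"))
  for (s in stack_opts)
    for (h in hb_opts)
      for (hh in list(character(0), "H"))
        for (ii in list(character(0), "I"))
          for (jj in list(character(0), "J"))
            sets[[length(sets) + 1L]] <- c("A", s, h, hh, ii, jj)
  sets
}

#' Candidate base rings of a profile
#'
#' One evaluation context per ligand aromatic ring participating in at
#' least one pi-stacking interaction (pattern A is a prerequisite for
#' every other pattern). Each context carries the stacks to that ring,
#' the hydrogen bonds anchored on the ring moiety (ring members plus
#' atoms covalently bonded to a ring member), and the distal
#' anchor-to-centroid distances of every hydrogen bond, hydrophobic
#' contact and halogen bond of the profile.
#'
#' @param profile an \code{ip_profile}.
#' @return list of contexts (class \code{ip_ring_context}); empty when
#'   no ligand ring is stacked.
#' @export
candidate_base_rings <- function(profile) {
  site <- profile$site
  stacks <- profile$pistacks
  if (length(site$ligand_rings) == 0L || nrow(stacks) == 0L) return(list())
  out <- list()
  for (i in seq_along(site$ligand_rings)) {
    st <- stacks[stacks$ligand_ring == i, , drop = FALSE]
    if (nrow(st) == 0L) next
    ring <- site$ligand_rings[[i]]
    moiety <- .ring_moiety(site, ring)
    hb <- profile$hbonds
    hb_x <- if (nrow(hb) > 0L)
      .dist_to_centroid(site, hb$ligand_anchor_serial, ring$centroid) else
        numeric(0)
    moiety_idx <- which(hb$ligand_anchor_serial %in% moiety)
    dirs <- if (length(moiety_idx) > 0L)
      t(vapply(moiety_idx, function(k) {
        .model_xyz(site, hb$acceptor_serial[k]) -
          .model_xyz(site, hb$donor_serial[k])
      }, numeric(3))) else matrix(numeric(0), 0, 3)
    hp <- profile$hydrophobic
    hp_x <- if (nrow(hp) > 0L)
      .dist_to_centroid(site, hp$ligand_serial, ring$centroid) else numeric(0)
    xb <- profile$halogen_bonds
    xb_x <- if (nrow(xb) > 0L)
      .dist_to_centroid(site, xb$halogen_serial, ring$centroid) else numeric(0)
    out[[length(out) + 1L]] <- structure(list(
      ring_index = i,
      ring = ring,
      stacks = st,
      moiety_hbonds = hb[moiety_idx, , drop = FALSE],
      moiety_hbond_dirs = dirs,
      hbond_x = hb_x,
      hydrophobic_x = hp_x,
      halogen_x = xb_x
    ), class = "ip_ring_context")
  }
  out
}

.ring_moiety <- function(site, ring) {
  members <- ring$member_serials
  b <- site$bonds
  lig <- site$ligand_atoms$serial
  ext <- c(b[b[, 1] %in% members, 2], b[b[, 2] %in% members, 1])
  at <- site$model_atoms
  ext <- ext[at$element[match(ext, at$serial)] != "H"]
  sort(unique(c(members, intersect(ext, lig))))
}

.dist_to_centroid <- function(site, serials, centroid) {
  xyz <- .coords(site$atoms, serials)
  sqrt(rowSums(sweep(xyz, 2, centroid)^2))
}

#' Evaluate the patterns A-J on one base-ring context
#'
#' Pattern definitions: A base ring (true by construction); B at least
#' two stacks from distinct protein rings; C additionally two stacks on
#' strictly opposite faces; D additionally at least two parallel-type
#' stacks; E at least two distinct base-ring hydrogen bonds; F
#' additionally two bonds to the same protein residue; G additionally a
#' pair of bonds whose donor-to-acceptor direction vectors subtend an
#' angle within 180 +/- 18 degrees; H a hydrophobic contact, I a
#' hydrogen bond, J a halogen bond whose ligand anchor lies in the
#' respective strict distal band.
#'
#' @param context an \code{ip_ring_context} from
#'   \code{\link{candidate_base_rings}}.
#' @param config a \code{\link{pattern_config}}.
#' @return An object of class \code{ip_eval}: list with
#'   \code{ring_index}, \code{flags} (named logical A-J), \code{count},
#'   and \code{evidence} (per-pattern supporting measurements).
#' @export
evaluate_patterns <- function(context, config = pattern_config()) {
  flags <- stats::setNames(rep(FALSE, 10L), .PATTERNS)
  evidence <- list()
  flags["A"] <- nrow(context$stacks) >= 1L
  if (flags["A"]) evidence$A <- context$stacks

  st <- context$stacks
  distinct_rings <- unique(st$protein_ring)
  flags["B"] <- flags["A"] && length(distinct_rings) >= 2L
  if (flags["B"]) {
    evidence$B <- st
    signs <- st$face_sign
    flags["C"] <- any(signs == 1L) && any(signs == -1L)
    if (flags["C"]) evidence$C <- st[st$face_sign != 0L, , drop = FALSE]
    npar <- sum(st$stack_type == "parallel")
    flags["D"] <- npar >= 2L
    if (flags["D"]) evidence$D <- st[st$stack_type == "parallel", ,
                                     drop = FALSE]
  }

  mh <- context$moiety_hbonds
  flags["E"] <- flags["A"] && nrow(mh) >= 2L
  if (flags["E"]) {
    evidence$E <- mh
    res <- mh$protein_residue
    flags["F"] <- anyDuplicated(res) > 0L
    if (flags["F"]) evidence$F <- mh[res %in% res[duplicated(res)], ,
                                     drop = FALSE]
    dirs <- context$moiety_hbond_dirs
    lo <- config$parallel_hbond_angle_center - config$parallel_hbond_tolerance
    hi <- config$parallel_hbond_angle_center + config$parallel_hbond_tolerance
    best <- NULL
    for (a in seq_len(nrow(mh) - 1L)) {
      for (b in seq((a + 1L), nrow(mh))) {
        ang <- vec_angle(dirs[a, ], dirs[b, ])
        if (ang >= lo && ang <= hi) {
          flags["G"] <- TRUE
          if (is.null(best)) best <- data.frame(i = a, j = b, angle = ang)
        }
      }
    }
    if (flags["G"]) evidence$G <- best
  }

  if (flags["A"]) {
    bh <- config$distal_hydrophobic_band
    hx <- context$hydrophobic_x
    hit <- hx > bh[1] & hx < bh[2]
    flags["H"] <- any(hit)
    if (flags["H"]) evidence$H <- data.frame(x = hx[hit])

    bi <- config$distal_hbond_band
    ix <- context$hbond_x
    hit <- ix > bi[1] & ix < bi[2]
    flags["I"] <- any(hit)
    if (flags["I"]) evidence$I <- data.frame(x = ix[hit])

    bj <- config$distal_halogen_band
    jx <- context$halogen_x
    hit <- jx > bj[1] & jx < bj[2]
    flags["J"] <- any(hit)
    if (flags["J"]) evidence$J <- data.frame(x = jx[hit])
  }

  structure(list(ring_index = context$ring_index, flags = flags,
                 count = sum(flags), evidence = evidence),
            class = "ip_eval")
}

.empty_eval <- function() {
  structure(list(ring_index = NA_integer_,
                 flags = stats::setNames(rep(FALSE, 10L), .PATTERNS),
                 count = 0L, evidence = list()),
            class = "ip_eval")
}

#' Best pattern evaluation of a profile
#'
#' Evaluates every candidate base ring and returns the evaluation with
#' the maximal pattern count (ties resolved toward the lowest ring index
#' in canonical atom order). A profile without any stacked ligand ring
#' yields the all-false evaluation with count 0.
#'
#' @param profile an \code{ip_profile}.
#' @param config a \code{\link{pattern_config}}.
#' @return an \code{ip_eval}.
#' @export
best_evaluation <- function(profile, config = pattern_config()) {
  contexts <- candidate_base_rings(profile)
  if (length(contexts) == 0L) return(.empty_eval())
  evals <- lapply(contexts, evaluate_patterns, config = config)
  counts <- vapply(evals, `[[`, integer(1), "count")
  evals[[which.max(counts)]]  # which.max takes the first (lowest ring index)
}

#' Format an evaluation as a one-row report
#'
#' @param eval an \code{ip_eval}.
#' @param profile the profile it came from.
#' @return one-row data frame: structure_id, ligand_id, A..J as 0/1,
#'   count, base-ring atom names.
#' @export
evaluation_row <- function(eval, profile) {
  ring_atoms <- if (!is.na(eval$ring_index)) {
    ring <- profile$site$ligand_rings[[eval$ring_index]]
    paste(profile$site$atoms$name[
      match(ring$member_serials, profile$site$atoms$serial)],
      collapse = ",")
  } else ""
  cbind(data.frame(structure_id = profile$structure_id,
                   ligand_id = profile$ligand_id,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(as.integer(eval$flags)),
                      col.names = .PATTERNS),
        data.frame(count = eval$count, base_ring = ring_atoms,
                   stringsAsFactors = FALSE))
}
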