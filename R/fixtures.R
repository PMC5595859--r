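## Deterministic generator of synthetic binding-site structures in PDB
## format realizing any requested implication-closed subset of the
## patterns A-J. The ligand is a geometric test article: a planar
## pyrimidine-like six-ring (the base ring) with an exocyclic carbonyl
## oxygen and amine nitrogen (paired hydrogen-bond anchors), an
## aliphatic arm ending at the distal-hydrophobic band midpoint, a
## bromine arm ending at the distal-halogen band midpoint, and a
## hydroxyl arm at the distal-hydrogen-bond band midpoint. Protein
## partners (imidazole rings, amide/hydroxyl donors and acceptors,
## leucine-like carbons, backbone-like carbonyls) are placed only for
## the requested patterns.

.rot2 <- function(v, deg) {
  th <- deg * pi / 180
  c(cos(th) * v[1] - sin(th) * v[2], sin(th) * v[1] + cos(th) * v[2], 0)
}

## Extend a planar chain: next atom at bond length `bond` from `prev`
## landing at distance `target` from the origin (bending counter-
## clockwise when needed).
.extend <- function(prev, bond, target) {
  r <- sqrt(sum(prev[1:2]^2))
  a <- c(prev[1:2] / r, 0)
  cosphi <- (target^2 - r^2 - bond^2) / (2 * bond * r)
  if (cosphi > 1 || cosphi < -1)
    stop("chain extension infeasible: target radius ", target)
  sinphi <- sqrt(1 - cosphi^2)
  perp <- c(-a[2], a[1], 0)
  prev + bond * (cosphi * a + sinphi * perp)
}

## Imidazole-like 5-ring: center, unit normal, circumradius 1.16,
## base angle beta; elements C,N,C,N,C in ring order.
.imidazole <- function(center, normal, beta) {
  e1 <- if (abs(normal[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
  e1 <- unit(e1 - sum(e1 * normal) * normal)
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  ang <- (beta + 72 * (0:4)) * pi / 180
  xyz <- t(vapply(ang, function(a)
    center + 1.16 * (cos(a) * e1 + sin(a) * e2), numeric(3)))
  list(xyz = xyz, names = c("CG", "ND1", "CE1", "NE2", "CD2"),
       elements = c("C", "N", "C", "N", "C"))
}

#' Build a synthetic binding-site fixture for a pattern set
#'
#' Generates a PDB-format structure whose best pattern evaluation is
#' exactly the requested set. The requested set must be closed under
#' the pattern implications. With \code{self_check = TRUE} the
#' generated structure is parsed, profiled and evaluated, and a
#' mismatch with the requested set raises an error.
#'
#' @param patterns character vector of pattern letters (subset of A-J);
#'   the empty set yields a ligand with no protein partners.
#' @param stack_distance ring-plane separation of parallel stacks
#'   (default 3.5 A).
#' @param hbond_length donor-acceptor distance of the paired hydrogen
#'   bonds (default 2.9 A).
#' @param distal named vector of anchor-to-centroid radii for the
#'   distal patterns (defaults: H 5.25, I 5.75, J 8.5 -- the band
#'   midpoints).
#' @param component ligand component code (3 characters).
#' @param id structure identifier.
#' @param self_check verify the fixture by profiling it (default TRUE).
#' @return list of class \code{ip_fixture} with \code{id},
#'   \code{patterns} (sorted), \code{pdb} (character vector of PDB
#'   lines), and \code{expected} (named logical flags A-J).
#' @export
build_fixture <- function(patterns = "A",
                          stack_distance = 3.5,
                          hbond_length = 2.9,
                          distal = c(H = 5.25, I = 5.75, J = 8.5),
                          component = "LIG",
                          id = NULL,
                          self_check = TRUE) {
  patterns <- sort(unique(toupper(patterns)))
  if (length(patterns) > 0L && !all(patterns %in% LETTERS[1:10]))
    stop("unknown pattern letter(s): ",
         paste(setdiff(patterns, LETTERS[1:10]), collapse = ", "))
  ok <- is_closed_pattern_set(patterns)
  if (!isTRUE(ok))
    stop("pattern set not implication-closed: ", attr(ok, "violation"))
  if (is.null(id)) id <- paste0("FX", paste(patterns, collapse = ""))
  has <- function(p) p %in% patterns
  sd <- stack_distance
  h <- hbond_length

  r6 <- 1.39
  ringang <- c(180, 240, 300, 0, 60, 120) * pi / 180
  ringxyz <- t(vapply(ringang, function(a) r6 * c(cos(a), sin(a), 0),
                      numeric(3)))
  atoms <- list()
  add <- function(name, element, xyz, resname, chain, resno, het) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      name = name, element = element, x = xyz[1], y = xyz[2], z = xyz[3],
      resname = resname, chain = chain, resno = resno, het = het,
      stringsAsFactors = FALSE)
  }
  ligadd <- function(name, element, xyz)
    add(name, element, xyz, component, "L", 900L, TRUE)

  # --- ligand ---------------------------------------------------------
  ringnm <- c("N1", "C2", "N3", "C4", "C5", "C6")
  ringel <- c("N", "C", "N", "C", "C", "C")
  for (i in 1:6) ligadd(ringnm[i], ringel[i], ringxyz[i, ])
  C2 <- ringxyz[2, ]; C4 <- ringxyz[4, ]; C5 <- ringxyz[5, ]
  C6 <- ringxyz[6, ]; N1 <- ringxyz[1, ]
  O4 <- C4 + 1.23 * c(1, 0, 0)
  N7 <- C5 + 1.34 * c(cos(pi / 3), sin(pi / 3), 0)
  ligadd("O4", "O", O4)
  ligadd("N7", "N", N7)
  u240 <- c(cos(4 * pi / 3), sin(4 * pi / 3), 0)
  C8 <- C2 + 1.5 * u240
  C9 <- C8 + 1.5 * u240
  C10 <- .extend(C9, 1.5, distal[["H"]])
  ligadd("C8", "C", C8); ligadd("C9", "C", C9); ligadd("C10", "C", C10)
  u120 <- c(cos(2 * pi / 3), sin(2 * pi / 3), 0)
  C11 <- C6 + 1.5 * u120
  C12 <- C11 + 1.5 * u120
  C13 <- C12 + 1.5 * u120
  C14 <- C13 + 1.5 * u120
  BR <- .extend(C14, 1.9, distal[["J"]])
  ligadd("C11", "C", C11); ligadd("C12", "C", C12)
  ligadd("C13", "C", C13); ligadd("C14", "C", C14)
  ligadd("BR15", "BR", BR)
  C15 <- N1 + 1.47 * c(-1, 0, 0)
  C16 <- C15 + 1.53 * c(-1, 0, 0)
  O17 <- .extend(C16, 1.43, distal[["I"]])
  ligadd("C15", "C", C15); ligadd("C16", "C", C16)
  ligadd("O17", "O", O17)

  # --- protein partners ----------------------------------------------
  zsgn <- 1
  if (has("A")) {
    # base stack: parallel imidazole above the ring plane
    im <- .imidazole(c(0, 0, sd), c(0, 0, 1), beta = 78)
    for (i in 1:5) add(im$names[i], im$elements[i], im$xyz[i, ],
                       "HIS", "P", 10L, FALSE)
  }
  if (has("B")) {
    if (has("C") && has("D")) {        # second parallel ring, below
      im <- .imidazole(c(0, 0, -sd), c(0, 0, 1), beta = 78)
    } else if (has("D")) {
      # second parallel ring stacked on the same face, twisted by 36
      # degrees so the atoms interleave with the first ring's
      im <- .imidazole(c(0, 0, sd + 1.9), c(0, 0, 1), beta = 114)
    } else if (has("C")) {             # T-shaped ring, below
      im <- .imidazole(c(1.5, 0, -(sd + 1.0)), c(1, 0, 0), beta = 108)
    } else {
      # edge-to-face ring in the ligand plane (face sign exactly 0, so
      # neither face-opposition nor a second parallel stack arises)
      ctr <- 4.9 * c(cos(-pi / 3), sin(-pi / 3), 0)
      im <- .imidazole(ctr, unit(ctr), beta = 0)
    }
    for (i in 1:5) add(im$names[i], im$elements[i], im$xyz[i, ],
                       "HIS", "P", 11L, FALSE)
  }
  if (has("E")) {
    # donor partner opposite the carbonyl O4
    Dp <- O4 + c(h, 0, 0)
    Dn <- Dp + (if (has("F")) 1.33 else 1.43) *
      c(cos(pi / 3), sin(pi / 3), 0)
    if (has("F")) {
      add("NE2", "N", Dp, "GLN", "P", 20L, FALSE)
      add("CD", "C", Dn, "GLN", "P", 20L, FALSE)
    } else {
      add("OG", "O", Dp, "SER", "P", 21L, FALSE)
      add("CB", "C", Dn, "SER", "P", 21L, FALSE)
    }
    # acceptor partner for the ligand amine N7; the direction sets the
    # angle between the two donor->acceptor vectors (pattern G)
    theta2 <- if (has("G")) -10 else 60
    OE1 <- N7 + h * .rot2(c(1, 0, 0), theta2)
    CO <- OE1 + 1.23 * c(0, 1, 0)
    add("OE1", "O", OE1, "GLN", "P", 20L, FALSE)
    add("CG", "C", CO, "GLN", "P", 20L, FALSE)
  }
  if (has("H")) {
    CD1 <- C10 + 3.6 * unit(c(C10[1:2], 0))
    CGl <- C10 + 5.13 * unit(c(C10[1:2], 0))
    add("CD1", "C", CD1, "LEU", "P", 30L, FALSE)
    add("CG", "C", CGl, "LEU", "P", 30L, FALSE)
  }
  if (has("I")) {
    OI <- O17 + 2.9 * unit(c(O17[1:2], 0))
    CI <- OI + 1.23 * .rot2(unit(c(OI[1:2], 0)), 90)
    add("O", "O", OI, "GLY", "P", 40L, FALSE)
    add("C", "C", CI, "GLY", "P", 40L, FALSE)
  }
  if (has("J")) {
    u <- unit(BR - C14)
    w <- .rot2(u, 10)
    OJ <- BR + 3.3 * w
    CJ <- OJ + 1.23 * .rot2(-w, 120)
    add("O", "O", OJ, "GLY", "P", 41L, FALSE)
    add("C", "C", CJ, "GLY", "P", 41L, FALSE)
  }

  tab <- do.call(rbind, atoms)
  tab$serial <- seq_len(nrow(tab))
  pdb <- .format_pdb(tab, id)

  out <- structure(list(id = id, patterns = patterns, pdb = pdb,
                        expected = stats::setNames(
                          LETTERS[1:10] %in% patterns, LETTERS[1:10])),
                   class = "ip_fixture")
  if (self_check) {
    ev <- evaluate_fixture(out)
    got <- names(ev$flags)[ev$flags]
    if (!identical(sort(got), patterns))
      stop("fixture self-check failed for {",
           paste(patterns, collapse = ""), "}: evaluated to {",
           paste(got, collapse = ""), "}")
  }
  out
}

#' Profile and evaluate a fixture
#'
#' Round-trips a fixture through the full pipeline: parse, select the
#' ligand, carve the binding site, profile, and return the best pattern
#' evaluation.
#'
#' @param fixture an \code{ip_fixture}.
#' @param config detection configuration.
#' @param pattern_cfg pattern configuration.
#' @return an \code{ip_eval}.
#' @export
evaluate_fixture <- function(fixture, config = interaction_config(),
                             pattern_cfg = pattern_config()) {
  model <- parse_structure(fixture$pdb, format = "pdb", id = fixture$id)
  ligs <- select_ligands(model)
  if (length(ligs) == 0L) return(.empty_eval())
  site <- build_binding_site(model, ligs[[1L]],
                             include_fluorine = config$include_fluorine)
  best_evaluation(profile_complex(site, config), pattern_cfg)
}

.format_pdb <- function(tab, id) {
  lines <- c(sprintf("HEADER    SYNTHETIC FIXTURE                       %s",
                     id))
  for (i in seq_len(nrow(tab))) {
    nm <- tab$name[i]
    nm4 <- if (nchar(nm) >= 4L) substr(nm, 1, 4) else
      sprintf("%-3s", nm)
    nm4 <- if (nchar(nm) >= 4L) nm4 else paste0(" ", nm4)
    lines <- c(lines, sprintf(
      "%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      if (tab$het[i]) "HETATM" else "ATOM", tab$serial[i], nm4,
      tab$resname[i], tab$chain[i], tab$resno[i],
      tab$x[i], tab$y[i], tab$z[i], 1.0, 0.0, tab$element[i]))
  }
  c(lines, "END")
}

#' Generate a deterministic library of fixtures
#'
#' Cycles through all implication-closed pattern subsets, jittering the
#' distal placements within the band interiors and the stack distance
#' slightly; deterministic for a given seed. Component codes are unique
#' by default but may repeat (to exercise per-ligand aggregation) via
#' \code{components}.
#'
#' @param n number of fixtures.
#' @param seed integer seed.
#' @param components optional character vector of length \code{n} of
#'   ligand component codes.
#' @return list of \code{ip_fixture} objects; each carries its planted
#'   pattern set in \code{$patterns} and its component code in
#'   \code{$component}.
#' @export
fixture_library <- function(n, seed = 1L, components = NULL) {
  stopifnot(n >= 1L)
  sets <- closed_pattern_sets()
  if (is.null(components)) {
    alphabet <- c(0:9, LETTERS)
    components <- vapply(seq_len(n), function(i) {
      paste0("L", alphabet[(i - 1) %/% 36 + 1], alphabet[(i - 1) %% 36 + 1])
    }, character(1))
  }
  stopifnot(length(components) == n)
  out <- vector("list", n)
  set.seed(seed)
  for (i in seq_len(n)) {
    set <- sets[[(i - 1L) %% length(sets) + 1L]]
    jit <- stats::runif(4, -1, 1)
    fx <- build_fixture(
      patterns = set,
      stack_distance = 3.5 + 0.1 * jit[1],
      hbond_length = 2.9 + 0.05 * jit[2],
      distal = c(H = 5.25 + 0.2 * jit[3], I = 5.75 + 0.05 * jit[4],
                 J = 8.5 + 0.2 * jit[1]),
      component = components[i],
      id = sprintf("FX%04d", i),
      self_check = FALSE)
    fx$component <- components[i]
    out[[i]] <- fx
  }
  out
}

#' Write a fixture (or library) to PDB files
#'
#' @param fixtures an \code{ip_fixture} or list of them.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_fixtures <- function(fixtures, dir) {
  if (inherits(fixtures, "ip_fixture")) fixtures <- list(fixtures)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(fixtures, function(fx) {
    p <- file.path(dir, paste0(fx$id, ".pdb"))
    writeLines(fx$pdb, p)
    p
  }, character(1))
  invisible(paths)
}
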