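## Structure parsing, ligand selection, binding-site carving, aromatic ring
## perception and interaction-capability typing of atoms.
##
## All operations work on heavy atoms; explicit hydrogens are used when
## present but never required (see the methods vignette for the surrogate
## donor criteria used when they are absent).

# Covalent radii (Angstrom), Cordero et al. consensus values.
.COVALENT_RADII <- c(
  "H" = 0.31, "C" = 0.76, "N" = 0.71, "O" = 0.66, "S" = 1.05, "P" = 1.07,
  "F" = 0.57, "CL" = 1.02, "BR" = 1.20, "I" = 1.39, "B" = 0.84,
  "SE" = 1.20, "FE" = 1.32, "ZN" = 1.22, "MG" = 1.41, "MN" = 1.39,
  "CA" = 1.76, "NA" = 1.66, "K" = 2.03, "CU" = 1.32, "NI" = 1.24,
  "CO" = 1.26, "MO" = 1.54, "W" = 1.62
)

.WATER_CODES <- c("HOH", "DOD", "WAT", "H2O")

.elem_from_name <- function(name) {
  s <- gsub("[^A-Za-z]", "", name)
  s <- toupper(s)
  two <- substr(s, 1, 2)
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "SE", "NA", "NI",
                    "CU", "CO", "MO"),
         two, substr(s, 1, 1))
}

#' Parse a protein-ligand structure
#'
#' Reads a PDB (or mmCIF) file into a structure model: an atom table with
#' residue and chain bookkeeping plus inferred covalent bonds. Only the
#' first model of multi-model files is used. Alternate locations are
#' resolved to the highest-occupancy conformer (ties go to altloc
#' \code{"A"}). Covalent bonds are inferred from interatomic distances
#' (sum of covalent radii plus a slack of \code{bond_slack} Angstrom);
#' CONECT records, when present, supplement the inferred set.
#'
#' @param source path to a structure file, or a character vector of PDB
#'   lines (anything containing a newline or more than one element is
#'   treated as file content, not a path).
#' @param format \code{"pdb"} or \code{"cif"}.
#' @param id structure identifier; defaults to the file base name.
#' @param bond_slack slack added to the covalent-radius sum (Angstrom).
#' @return An object of class \code{ip_structure}: a list with
#'   \code{id}, \code{atoms} (data frame with columns serial, name,
#'   element, x, y, z, resname, resno, chain, het, altloc) and
#'   \code{bonds} (two-column integer matrix of atom serials).
#' @export
parse_structure <- function(source, format = c("pdb", "cif"), id = NULL,
                            bond_slack = 0.45) {
  format <- match.arg(format)
  is_content <- length(source) > 1L || grepl("\n", source[1L]) ||
    grepl("^(ATOM|HETATM)", source[1L])
  if (is_content) {
    path <- tempfile(fileext = paste0(".", format))
    on.exit(unlink(path), add = TRUE)
    writeLines(if (length(source) > 1L) source else
      strsplit(source, "\n", fixed = TRUE)[[1L]], path)
  } else {
    path <- source
    if (!file.exists(path))
      stop("cannot read structure file: ", path)
  }
  if (is.null(id)) {
    id <- if (is_content) "structure" else
      sub("\\.(pdb|ent|cif)(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  }

  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, rm.alt = FALSE, multi = FALSE,
                                         verbose = FALSE)
    else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (nrow(at) == 0L) stop("empty structure: ", id)

  elem <- toupper(trimws(as.character(at$elesy)))
  miss <- is.na(elem) | elem == ""
  if (any(miss)) elem[miss] <- .elem_from_name(at$elety[miss])

  atoms <- data.frame(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    element = elem,
    x = at$x, y = at$y, z = at$z,
    resname = trimws(at$resid),
    resno = as.integer(at$resno),
    chain = ifelse(is.na(at$chain), "", as.character(at$chain)),
    het = at$type == "HETATM",
    altloc = ifelse(is.na(at$alt), "", as.character(at$alt)),
    occ = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE
  )
  atoms <- .resolve_altlocs(atoms)
  atoms$occ <- NULL
  if (anyDuplicated(atoms$serial))
    stop("duplicate atom serials in ", id)
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite coordinates in ", id)

  conect <- if (format == "pdb") .read_conect(path, atoms$serial) else NULL
  bonds <- infer_bonds(atoms, slack = bond_slack, extra = conect)

  structure(list(id = id, atoms = atoms, bonds = bonds),
            class = "ip_structure")
}

## Keep, per (chain, resno, resname, atom name), the highest-occupancy
## altloc; ties resolved by altloc letter ascending (so 'A' wins).
.resolve_altlocs <- function(atoms) {
  has_alt <- atoms$altloc != ""
  if (!any(has_alt)) return(atoms)
  key <- paste(atoms$chain, atoms$resno, atoms$resname, atoms$name, sep = "\r")
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[has_alt])) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    ord <- order(-atoms$occ[idx], atoms$altloc[idx])
    keep[idx[-ord[1L]]] <- FALSE
  }
  atoms[keep, , drop = FALSE]
}

.read_conect <- function(path, serials) {
  lines <- grep("^CONECT", readLines(path, warn = FALSE), value = TRUE)
  if (length(lines) == 0L) return(NULL)
  out <- list()
  for (ln in lines) {
    flds <- suppressWarnings(as.integer(
      substring(ln, seq(7, 27, by = 5), seq(11, 31, by = 5))))
    flds <- flds[!is.na(flds)]
    if (length(flds) >= 2L) {
      a <- flds[1L]
      for (b in flds[-1L]) out[[length(out) + 1L]] <- c(min(a, b), max(a, b))
    }
  }
  if (length(out) == 0L) return(NULL)
  m <- unique(do.call(rbind, out))
  m[m[, 1] %in% serials & m[, 2] %in% serials, , drop = FALSE]
}

#' Infer covalent bonds from interatomic distances
#'
#' Two atoms are bonded when their distance does not exceed the sum of
#' their covalent radii plus \code{slack}. A grid-based neighbor search
#' keeps this linear in the number of atoms; it is tested for equality
#' against a brute-force all-pairs scan.
#'
#' @param atoms atom table (as in \code{\link{parse_structure}}).
#' @param slack distance slack in Angstrom (default 0.45).
#' @param extra optional two-column matrix of additional bonds (serials),
#'   e.g. from CONECT records.
#' @return two-column integer matrix of bonded atom serials
#'   (\code{from < to}), zero rows when there are no bonds.
#' @export
infer_bonds <- function(atoms, slack = 0.45, extra = NULL) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- .COVALENT_RADII[atoms$element]
  rad[is.na(rad)] <- 1.5  # conservative default for exotic elements
  maxcut <- 2 * max(rad) + slack
  pairs <- neighbor_pairs(xyz, maxcut)
  out <- NULL
  if (nrow(pairs) > 0L) {
    i <- pairs[, 1]; j <- pairs[, 2]
    ok <- pairs[, 3] <= rad[i] + rad[j] + slack & pairs[, 3] > 0.4
    i <- i[ok]; j <- j[ok]
    out <- cbind(pmin(atoms$serial[i], atoms$serial[j]),
                 pmax(atoms$serial[i], atoms$serial[j]))
  }
  if (!is.null(extra) && nrow(extra) > 0L)
    out <- rbind(out, cbind(pmin(extra[, 1], extra[, 2]),
                            pmax(extra[, 1], extra[, 2])))
  if (is.null(out) || nrow(out) == 0L)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("from", "to"))))
  out <- unique(out[out[, 1] != out[, 2], , drop = FALSE])
  out <- out[order(out[, 1], out[, 2]), , drop = FALSE]
  dimnames(out) <- list(NULL, c("from", "to"))
  storage.mode(out) <- "integer"
  out
}

## Grid (cell-list) neighbor search: all index pairs i < j with
## distance <= cutoff; returns matrix with columns i, j, dist.
neighbor_pairs <- function(xyz, cutoff) {
  n <- nrow(xyz)
  if (n < 2L)
    return(matrix(numeric(0), 0, 3))
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cutoff)
  key <- paste(cell[, 1], cell[, 2], cell[, 3], sep = ",")
  bins <- split(seq_len(n), key)
  coords <- lapply(strsplit(names(bins), ","), as.numeric)
  res <- list()
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keymap <- stats::setNames(seq_along(bins), names(bins))
  for (b in seq_along(bins)) {
    cc <- coords[[b]]
    ii <- bins[[b]]
    for (o in seq_len(nrow(offsets))) {
      nb <- cc + offsets[o, ]
      nbkey <- paste(nb[1], nb[2], nb[3], sep = ",")
      b2 <- keymap[nbkey]
      if (is.na(b2) || b2 < b) next
      jj <- bins[[b2]]
      d <- cross_dist(xyz[ii, , drop = FALSE], xyz[jj, , drop = FALSE])
      hit <- which(d <= cutoff, arr.ind = TRUE)
      if (nrow(hit) == 0L) next
      gi <- ii[hit[, 1]]; gj <- jj[hit[, 2]]
      keep <- if (b2 == b) gi < gj else rep(TRUE, length(gi))
      if (any(keep))
        res[[length(res) + 1L]] <-
          cbind(pmin(gi, gj)[keep], pmax(gi, gj)[keep], d[hit][keep])
    }
  }
  if (length(res) == 0L) return(matrix(numeric(0), 0, 3))
  unique(do.call(rbind, res))
}

#' Select ligand instances from a structure
#'
#' Hetero residues excluding water and an exclusion set of component
#' codes; one selection per residue instance. When an allowlist is given
#' (BioLiP-style discrimination of biologically relevant ligands from
#' crystallization artifacts), only instances present in it are kept.
#'
#' @param model an \code{ip_structure}.
#' @param exclusion character vector of excluded component codes
#'   (water codes are always excluded).
#' @param allowlist optional data frame with columns \code{structure_id},
#'   \code{component_id}, \code{chain}, \code{residue_number}
#'   (see \code{\link{read_allowlist}}).
#' @return list of ligand selections, each a list with
#'   \code{component_id}, \code{chain}, \code{residue_number},
#'   \code{atom_serials}.
#' @export
select_ligands <- function(model, exclusion = character(0), allowlist = NULL) {
  at <- model$atoms
  het <- at[at$het & !(at$resname %in% c(.WATER_CODES, exclusion)), ,
            drop = FALSE]
  if (nrow(het) == 0L) return(list())
  key <- paste(het$resname, het$chain, het$resno, sep = "\r")
  out <- lapply(split(seq_len(nrow(het)), key), function(idx) {
    list(component_id = het$resname[idx[1L]],
         chain = het$chain[idx[1L]],
         residue_number = het$resno[idx[1L]],
         atom_serials = het$serial[idx])
  })
  out <- out[order(names(out))]
  names(out) <- NULL
  if (!is.null(allowlist)) {
    wanted <- paste(allowlist$structure_id, allowlist$component_id,
                    allowlist$chain, allowlist$residue_number, sep = "\r")
    out <- Filter(function(l) {
      paste(model$id, l$component_id, l$chain, l$residue_number,
            sep = "\r") %in% wanted
    }, out)
  }
  out
}

#' Read a BioLiP-style ligand allowlist
#'
#' Tab-separated file with columns \code{structure_id},
#' \code{component_id}, \code{chain}, \code{residue_number}.
#'
#' @param path file path.
#' @return data frame with the four columns.
#' @export
read_allowlist <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("structure_id", "component_id", "chain", "residue_number")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("allowlist is missing column(s): ", paste(missing, collapse = ", "))
  tab
}

#' Carve a binding-site complex around one ligand instance
#'
#' Protein atoms are the non-hetero atoms whose minimum distance to any
#' ligand atom is at most \code{cutoff}. Aromatic rings are perceived on
#' both sides and every atom of the complex is typed by interaction
#' capability (see \code{\link{classify_atoms}}).
#'
#' @param model an \code{ip_structure}.
#' @param ligand a ligand selection from \code{\link{select_ligands}}.
#' @param cutoff binding-site distance cutoff in Angstrom (default 7.5).
#' @param include_fluorine treat fluorine as a halogen-bond donor
#'   (default \code{FALSE}).
#' @return An object of class \code{ip_site}: list with
#'   \code{structure_id}, \code{ligand}, \code{ligand_atoms},
#'   \code{protein_atoms}, \code{bonds} (full-model bonds, for neighbor
#'   context), \code{ligand_rings}, \code{protein_rings}, \code{classes}.
#' @export
build_binding_site <- function(model, ligand, cutoff = 7.5,
                               include_fluorine = FALSE) {
  if (cutoff <= 0) stop("cutoff must be positive")
  at <- model$atoms
  lig_idx <- match(ligand$atom_serials, at$serial)
  if (anyNA(lig_idx))
    stop("ligand atoms missing from model: ",
         paste(ligand$atom_serials[is.na(lig_idx)], collapse = ", "))
  lig_atoms <- at[lig_idx, , drop = FALSE]
  prot <- at[!at$het, , drop = FALSE]
  if (nrow(prot) > 0L) {
    d <- cross_dist(as.matrix(lig_atoms[, c("x", "y", "z")]),
                    as.matrix(prot[, c("x", "y", "z")]))
    keep <- apply(d, 2, min) <= cutoff
    prot <- prot[keep, , drop = FALSE]
  }
  site_atoms <- rbind(lig_atoms, prot)
  lig_rings <- perceive_aromatic_rings(lig_atoms, model$bonds)
  prot_rings <- perceive_aromatic_rings(prot, model$bonds)
  for (i in seq_along(lig_rings)) lig_rings[[i]]$owner <- "ligand"
  for (i in seq_along(prot_rings)) prot_rings[[i]]$owner <- "protein"
  site <- structure(list(
    structure_id = model$id,
    ligand = ligand,
    ligand_atoms = lig_atoms,
    protein_atoms = prot,
    atoms = site_atoms,
    bonds = model$bonds,
    model_atoms = model$atoms,
    ligand_rings = lig_rings,
    protein_rings = prot_rings,
    cutoff = cutoff
  ), class = "ip_site")
  site$classes <- classify_atoms(site, include_fluorine = include_fluorine)
  site
}

#' Perceive aromatic rings
#'
#' Smallest rings of size 5 or 6 on the inferred bond graph whose member
#' atoms are all aromatic-capable elements (C, N, O, S) and lie in a
#' common plane within \code{planarity_tol}. The ring normal is the unit
#' eigenvector of the smallest covariance eigenvalue with its sign
#' canonicalized (positive component along +z, ties along +x then +y),
#' so it is independent of atom input order.
#'
#' @param atoms atom table subset.
#' @param bonds full bond matrix (serials).
#' @param planarity_tol maximal out-of-plane deviation (default 0.15 A).
#' @return list of rings; each ring is a list with \code{member_serials}
#'   (in ring-path order), \code{centroid}, \code{normal}, \code{owner},
#'   \code{residue} tag. Rings are ordered by smallest member serial.
#' @export
perceive_aromatic_rings <- function(atoms, bonds, planarity_tol = 0.15) {
  ok <- atoms$element %in% c("C", "N", "O", "S")
  cand <- atoms[ok, , drop = FALSE]
  if (nrow(cand) < 5L) return(list())
  b <- bonds[bonds[, 1] %in% cand$serial & bonds[, 2] %in% cand$serial, ,
             drop = FALSE]
  if (nrow(b) == 0L) return(list())
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(b[, 1]), to = as.character(b[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(cand$serial)))
  seen <- character(0)
  rings <- list()
  for (e in seq_len(nrow(b))) {
    u <- as.character(b[e, 1]); v <- as.character(b[e, 2])
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(u, v)))
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = u, to = v,
                                                  output = "vpath"))
    path <- sp$vpath[[1L]]
    if (length(path) < 5L || length(path) > 6L) next
    members <- as.integer(names(path))
    sig <- paste(sort(members), collapse = ",")
    if (sig %in% seen) next
    seen <- c(seen, sig)
    idx <- match(members, atoms$serial)
    xyz <- as.matrix(atoms[idx, c("x", "y", "z")])
    pl <- fit_plane(xyz)
    if (pl$max_dev > planarity_tol) next
    rings[[length(rings) + 1L]] <- list(
      member_serials = members,
      centroid = pl$centroid,
      normal = canonical_normal(unit(pl$normal)),
      owner = NA_character_,
      residue = paste0(atoms$chain[idx[1L]], ":", atoms$resname[idx[1L]],
                       atoms$resno[idx[1L]])
    )
  }
  if (length(rings) > 1L) {
    ord <- order(vapply(rings, function(r) min(r$member_serials), integer(1)))
    rings <- rings[ord]
  }
  rings
}

#' Type atoms of a binding-site complex by interaction capability
#'
#' Heavy-atom rules: a nitrogen or oxygen is a hydrogen-bond donor when
#' it carries an explicit hydrogen, or when its valence implies an
#' attachable hydrogen (hydroxyl-like oxygen, amine-like nitrogen);
#' aromatic ring nitrogens without hydrogen are treated as
#' pyridine-like acceptors. An oxygen bonded to a single heavy neighbor
#' closer than 1.32 A is carbonyl-like (acceptor only). A carbon bonded
#' only to carbon or hydrogen is hydrophobic. Cl, Br and I are
#' halogen-bond donors (F optionally).
#'
#' @param site an \code{ip_site}.
#' @param include_fluorine include F among halogens (default FALSE).
#' @return data frame with columns \code{serial}, \code{hbond_donor},
#'   \code{hbond_acceptor}, \code{hydrophobic}, \code{halogen}.
#' @export
classify_atoms <- function(site, include_fluorine = FALSE) {
  atoms <- site$atoms
  all_atoms <- if (!is.null(site$model_atoms)) site$model_atoms else atoms
  bonds <- site$bonds
  ring_serials <- unique(unlist(c(
    lapply(site$ligand_rings, `[[`, "member_serials"),
    lapply(site$protein_rings, `[[`, "member_serials"))))

  nb <- .neighbor_map(bonds)
  elem_of <- stats::setNames(all_atoms$element, all_atoms$serial)
  coords_of <- all_atoms[, c("x", "y", "z")]
  rownames(coords_of) <- all_atoms$serial

  n <- nrow(atoms)
  donor <- acceptor <- hydrophobic <- halogen <- logical(n)
  hal_set <- c("CL", "BR", "I", if (include_fluorine) "F")

  for (i in seq_len(n)) {
    s <- atoms$serial[i]
    el <- atoms$element[i]
    nbs <- nb[[as.character(s)]]
    nb_el <- elem_of[as.character(nbs)]
    n_h <- sum(nb_el == "H", na.rm = TRUE)
    heavy <- nbs[!is.na(nb_el) & nb_el != "H"]
    heavy_el <- elem_of[as.character(heavy)]
    aromatic <- s %in% ring_serials

    if (el == "O") {
      if (length(heavy) == 0L) {
        donor[i] <- TRUE; acceptor[i] <- TRUE
      } else if (length(heavy) == 1L) {
        d <- sqrt(sum((as.numeric(coords_of[as.character(s), ]) -
                       as.numeric(coords_of[as.character(heavy), ]))^2))
        acceptor[i] <- TRUE
        donor[i] <- n_h > 0L || d >= 1.32  # hydroxyl-like single bond
      } else {
        acceptor[i] <- TRUE               # ether/ester-like
        donor[i] <- n_h > 0L
      }
    } else if (el == "N") {
      if (n_h > 0L) {
        donor[i] <- TRUE
        acceptor[i] <- !aromatic && length(heavy) <= 2L
      } else if (aromatic) {
        acceptor[i] <- length(heavy) <= 2L  # pyridine-like; N3-subst. neither
      } else if (length(heavy) >= 3L) {
        acceptor[i] <- TRUE                 # tertiary amine
      } else {
        donor[i] <- TRUE; acceptor[i] <- TRUE  # amine-like surrogate
      }
    } else if (el == "C") {
      hydrophobic[i] <- length(heavy) == 0L ||
        all(heavy_el %in% c("C", "H"))
    }
    if (el %in% hal_set) halogen[i] <- TRUE
  }
  data.frame(serial = atoms$serial, hbond_donor = donor,
             hbond_acceptor = acceptor, hydrophobic = hydrophobic,
             halogen = halogen)
}

.neighbor_map <- function(bonds) {
  nb <- list()
  if (nrow(bonds) == 0L) return(nb)
  for (k in seq_len(nrow(bonds))) {
    a <- as.character(bonds[k, 1]); b <- as.character(bonds[k, 2])
    nb[[a]] <- c(nb[[a]], bonds[k, 2])
    nb[[b]] <- c(nb[[b]], bonds[k, 1])
  }
  nb
}
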