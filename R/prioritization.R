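## Hit prioritization: scaffold-aware chemical-similarity clustering and
## the drug-class x target-superfamily repositioning evidence matrix
## with coverage statistics.

#' Pairwise chemical similarity matrix
#'
#' Tanimoto similarity on 2D atom-pair descriptors. Symmetric with
#' unit diagonal.
#'
#' @param compounds data frame with columns \code{component_id} and
#'   \code{smiles}.
#' @return list of class \code{ip_simmat}: \code{ids}, \code{matrix}.
#' @export
similarity_matrix <- function(compounds) {
  stopifnot(all(c("component_id", "smiles") %in% names(compounds)))
  n <- nrow(compounds)
  smi <- stats::setNames(compounds$smiles, compounds$component_id)
  sdf <- tryCatch(ChemmineR::smiles2sdf(smi), error = function(e)
    stop("failed to parse SMILES: ", conditionMessage(e), call. = FALSE))
  valid <- ChemmineR::validSDF(sdf)
  if (!all(valid))
    stop("unparseable structure notation for compound(s): ",
         paste(compounds$component_id[!valid], collapse = ", "))
  ap <- ChemmineR::sdf2ap(sdf)
  m <- matrix(NA_real_, n, n,
              dimnames = list(compounds$component_id,
                              compounds$component_id))
  for (i in seq_len(n)) {
    m[i, i] <- 1
    for (j in seq_len(i - 1L)) {
      s <- ChemmineR::cmp.similarity(ap[i], ap[j])
      m[i, j] <- s
      m[j, i] <- s
    }
  }
  structure(list(ids = compounds$component_id, matrix = m),
            class = "ip_simmat")
}

#' Scaffold-aware hierarchical clustering of compounds
#'
#' Compounds are grouped by scaffold label; within each scaffold,
#' average-linkage hierarchical clustering on distance = 1 - similarity
#' determines the leaf order. Scaffold groups are ordered
#' alphabetically and compounds are pre-sorted by id, so the result is
#' deterministic under permutation of the input.
#'
#' @param simmat an \code{ip_simmat} from \code{\link{similarity_matrix}}.
#' @param scaffolds named character vector mapping compound id to
#'   scaffold label; every compound must be labeled.
#' @return list of class \code{ip_clustering}: \code{order} (compound
#'   ids, scaffold groups contiguous), \code{scaffolds} (label per
#'   ordered compound), \code{dendrograms} (named list of
#'   \code{hclust} objects, singletons are \code{NULL}).
#' @export
cluster_within_scaffolds <- function(simmat, scaffolds) {
  ids <- simmat$ids
  missing <- setdiff(ids, names(scaffolds))
  if (length(missing))
    stop("missing scaffold label for compound(s): ",
         paste(missing, collapse = ", "))
  lab <- scaffolds[ids]
  ord <- character(0)
  dendros <- list()
  for (sc in sort(unique(lab))) {
    members <- sort(ids[lab == sc])
    if (length(members) == 1L) {
      ord <- c(ord, members)
      dendros[[sc]] <- NULL
      next
    }
    d <- stats::as.dist(1 - simmat$matrix[members, members])
    hc <- stats::hclust(d, method = "average")
    ord <- c(ord, members[hc$order])
    dendros[[sc]] <- hc
  }
  structure(list(order = ord, scaffolds = scaffolds[ord],
                 dendrograms = dendros),
            class = "ip_clustering")
}

#' Build the repositioning evidence matrix
#'
#' Aggregates compound-target evidence pairs onto a drug-class by
#' target-superfamily grid. A cell is \code{"structural"} when any
#' mapped pair has structural evidence, else \code{"other"} when any
#' has other evidence, else \code{"none"} (structural dominates).
#'
#' @param pairs data frame with columns \code{compound}, \code{target},
#'   \code{evidence} (values \code{structural} or \code{other}).
#' @param compound_classes named character vector: compound id ->
#'   drug-class label.
#' @param target_superfamilies named character vector: target id ->
#'   superfamily label.
#' @return list of class \code{ip_evidence}: \code{matrix} (character
#'   matrix, classes x superfamilies), \code{pairs} (the raw mapping).
#' @export
build_evidence_matrix <- function(pairs, compound_classes,
                                  target_superfamilies) {
  if (nrow(pairs) > 0L) {
    bad <- setdiff(pairs$evidence, c("structural", "other"))
    if (length(bad))
      stop("invalid evidence kind(s): ", paste(bad, collapse = ", "))
    un_c <- setdiff(unique(pairs$compound), names(compound_classes))
    un_t <- setdiff(unique(pairs$target), names(target_superfamilies))
    if (length(un_c) || length(un_t))
      stop("unmapped id(s): ", paste(c(un_c, un_t), collapse = ", "))
  }
  classes <- sort(unique(unname(compound_classes)))
  superfams <- sort(unique(unname(target_superfamilies)))
  m <- matrix("none", length(classes), length(superfams),
              dimnames = list(classes, superfams))
  if (nrow(pairs) > 0L) {
    cl <- compound_classes[pairs$compound]
    sf <- target_superfamilies[pairs$target]
    for (k in seq_len(nrow(pairs))) {
      cur <- m[cl[k], sf[k]]
      if (pairs$evidence[k] == "structural" || cur == "none")
        m[cl[k], sf[k]] <- pairs$evidence[k]
      # an existing "structural" is never overwritten by "other"
      if (cur == "structural") m[cl[k], sf[k]] <- "structural"
    }
  }
  structure(list(matrix = m, pairs = pairs), class = "ip_evidence")
}

#' Coverage statistics of an evidence matrix
#'
#' Percentages of grid cells with structural, other, or any binding
#' evidence, reported to one decimal place together with the
#' nearest-integer rendering.
#'
#' @param evidence an \code{ip_evidence}.
#' @return list with \code{n_total}, \code{n_structural},
#'   \code{n_other}, \code{pct_structural}, \code{pct_other},
#'   \code{pct_combined} (one decimal) and \code{pct_structural_int},
#'   \code{pct_combined_int}.
#' @export
coverage_stats <- function(evidence) {
  m <- evidence$matrix
  n <- length(m)
  if (n == 0L) stop("empty evidence matrix")
  ns <- sum(m == "structural")
  no <- sum(m == "other")
  pct <- function(x) round(100 * x / n, 1)
  list(n_total = n,
       n_structural = ns,
       n_other = no,
       pct_structural = pct(ns),
       pct_other = pct(no),
       pct_combined = pct(ns + no),
       pct_structural_int = round(100 * ns / n),
       pct_other_int = round(100 * no / n),
       pct_combined_int = round(100 * (ns + no) / n))
}
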