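## Collection-level screening: evaluate the patterns on every relevant
## ligand of every structure, aggregate per ligand (best complex), rank
## by pattern count and annotate drug status.

#' Screen a collection of structures for the patterns
#'
#' For each structure and each relevant ligand instance: carve the
#' binding site, profile it and take the best pattern evaluation.
#' Per-structure failures are logged and skipped; the run continues.
#'
#' @param paths character vector of structure file paths.
#' @param allowlist optional allowlist data frame
#'   (\code{\link{read_allowlist}}).
#' @param config detection configuration.
#' @param pattern_cfg pattern configuration.
#' @param cutoff binding-site cutoff in Angstrom.
#' @param exclusion component codes to exclude besides water.
#' @param log_file optional path; failures are appended to it.
#' @return data frame of complex scores: structure_id, component_id,
#'   chain, residue_number, A..J (0/1), count.
#' @export
screen_collection <- function(paths, allowlist = NULL,
                              config = interaction_config(),
                              pattern_cfg = pattern_config(),
                              cutoff = 7.5, exclusion = character(0),
                              log_file = NULL) {
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0L) stop("no readable structure files")
  logmsg <- function(msg) {
    if (!is.null(log_file)) cat(msg, "\n", file = log_file, append = TRUE)
  }
  rows <- list()
  for (p in paths) {
    fmt <- if (grepl("\\.cif$", p, ignore.case = TRUE)) "cif" else "pdb"
    model <- tryCatch(parse_structure(p, format = fmt),
                      error = function(e) {
                        logmsg(paste0("SKIP ", p, ": ", conditionMessage(e)))
                        NULL
                      })
    if (is.null(model)) next
    ligs <- select_ligands(model, exclusion = exclusion,
                           allowlist = allowlist)
    for (lig in ligs) {
      row <- tryCatch({
        site <- build_binding_site(model, lig, cutoff = cutoff,
                                   include_fluorine = config$include_fluorine)
        prof <- profile_complex(site, config)
        ev <- best_evaluation(prof, pattern_cfg)
        cbind(data.frame(structure_id = model$id,
                         component_id = lig$component_id,
                         chain = lig$chain,
                         residue_number = lig$residue_number,
                         stringsAsFactors = FALSE),
              as.data.frame(as.list(as.integer(ev$flags)),
                            col.names = LETTERS[1:10]),
              data.frame(count = ev$count))
      }, error = function(e) {
        logmsg(paste0("SKIP ", model$id, " ", lig$component_id, ": ",
                      conditionMessage(e)))
        NULL
      })
      if (!is.null(row)) rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L)
    return(data.frame(structure_id = character(0),
                      component_id = character(0), chain = character(0),
                      residue_number = integer(0), count = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate complex scores per ligand
#'
#' One entry per component id, keeping the complex with the highest
#' pattern count; ties go to the lexicographically smallest structure
#' id (then chain, then residue number).
#'
#' @param scores data frame from \code{\link{screen_collection}}.
#' @return data frame: component_id, best_count, best_structure,
#'   A..J flags of the best complex, n_complexes.
#' @export
aggregate_by_ligand <- function(scores) {
  if (nrow(scores) == 0L) stop("no complex scores to aggregate")
  out <- lapply(split(scores, scores$component_id), function(g) {
    g <- g[order(-g$count, g$structure_id, g$chain, g$residue_number), ,
           drop = FALSE]
    best <- g[1L, , drop = FALSE]
    cbind(data.frame(component_id = best$component_id,
                     best_count = best$count,
                     best_structure = best$structure_id,
                     stringsAsFactors = FALSE),
          best[, LETTERS[1:10], drop = FALSE],
          data.frame(n_complexes = nrow(g)))
  })
  out <- do.call(rbind, out[order(names(out))])
  rownames(out) <- NULL
  out
}

#' Rank ligands and annotate drug status
#'
#' Sorts the per-ligand aggregation by best pattern count (descending;
#' ties by component id ascending), flags hits with at least
#' \code{min_count} patterns, joins drug status from a user-supplied
#' table and tabulates the count histogram.
#'
#' @param rankings data frame from \code{\link{aggregate_by_ligand}}.
#' @param drug_table optional data frame with columns
#'   \code{component_id} and \code{drug_status} (one of none,
#'   experimental, clinical, approved).
#' @param min_count hit threshold (default 6 patterns).
#' @return list of class \code{ip_screen_report}: \code{table} (ranked
#'   data frame with rank, drug_status and is_hit columns),
#'   \code{histogram} (counts 0-10), \code{n_ligands}, \code{n_hits},
#'   \code{min_count}.
#' @export
rank_and_annotate <- function(rankings, drug_table = NULL, min_count = 6L) {
  tab <- rankings[order(-rankings$best_count, rankings$component_id), ,
                  drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$is_hit <- tab$best_count >= min_count
  tab$drug_status <- "none"
  if (!is.null(drug_table)) {
    need <- c("component_id", "drug_status")
    missing <- setdiff(need, names(drug_table))
    if (length(missing))
      stop("drug table is missing column(s): ",
           paste(missing, collapse = ", "))
    bad <- setdiff(drug_table$drug_status,
                   c("none", "experimental", "clinical", "approved"))
    if (length(bad))
      stop("invalid drug_status value(s): ", paste(bad, collapse = ", "))
    idx <- match(tab$component_id, drug_table$component_id)
    tab$drug_status[!is.na(idx)] <- drug_table$drug_status[idx[!is.na(idx)]]
  }
  hist <- table(factor(tab$best_count, levels = 0:10))
  tab <- tab[, c("rank", "component_id", "best_count", LETTERS[1:10],
                 "best_structure", "n_complexes", "drug_status", "is_hit")]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 histogram = stats::setNames(as.integer(hist), 0:10),
                 n_ligands = nrow(tab),
                 n_hits = sum(tab$is_hit),
                 min_count = min_count),
            class = "ip_screen_report")
}

#' Write a screen report to TSV and/or JSON
#'
#' @param report an \code{ip_screen_report}.
#' @param tsv,json optional output paths.
#' @return the report, invisibly.
#' @export
write_screen_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    utils::write.table(report$table, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json)) {
    obj <- list(ranking = report$table,
                histogram = as.list(report$histogram),
                n_ligands = report$n_ligands,
                n_hits = report$n_hits,
                min_count = report$min_count)
    writeLines(jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                                digits = NA), json)
  }
  invisible(report)
}

#' @export
print.ip_screen_report <- function(x, ...) {
  cat("Interaction-pattern screen:", x$n_ligands, "ligands,",
      x$n_hits, "hits with >=", x$min_count, "patterns\n")
  cat("Count histogram (0-10):", paste(x$histogram, collapse = " "), "\n")
  print(utils::head(x$table, 10))
  invisible(x)
}
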