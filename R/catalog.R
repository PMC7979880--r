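# Compound catalogs (biological / bioactive / chemical), popularity
# annotation, candidate filtering and ranking.

#' Load compound catalogs from TSV files
#'
#' Each catalog file is a TSV with columns `name`, `smiles`, `database`,
#' `identifier`. Structures are parsed and canonical keys computed, so catalog
#' membership is decided on constitution, not on names.
#'
#' @param paths named character vector of file paths; names are the catalog
#'   classes, a subset of `biological`, `bioactive`, `chemical`.
#' @return a `dn_catalogs` object: named list of `dn_catalog` tables.
#' @export
load_catalogs <- function(paths) {
  cls <- names(paths)
  if (is.null(cls) || !all(cls %in% c("biological", "bioactive", "chemical")))
    .dn_stop("dn_config_error",
             "catalog paths must be named biological/bioactive/chemical")
  out <- lapply(seq_along(paths), function(i) {
    if (!file.exists(paths[[i]]))
      .dn_stop("dn_config_error", "catalog file '%s' does not exist", paths[[i]])
    df <- utils::read.delim(paths[[i]], stringsAsFactors = FALSE)
    need <- c("name", "smiles", "database", "identifier")
    if (!all(need %in% names(df)))
      .dn_stop("dn_config_error", "catalog '%s' must have columns %s",
               paths[[i]], paste(need, collapse = ", "))
    df$key <- vapply(seq_len(nrow(df)), function(j)
      parse_structure(df$smiles[j], "smiles", name = df$name[j])$canonical_key,
      character(1))
    structure(df, class = c("dn_catalog", "data.frame"), catalog_class = cls[i])
  })
  names(out) <- cls
  structure(out, class = "dn_catalogs")
}

#' Write a catalog back to TSV
#'
#' @param catalog a `dn_catalog` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog_tsv <- function(catalog, path) {
  df <- as.data.frame(catalog)[, c("name", "smiles", "database", "identifier")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Key-indexed lookup over a catalog collection
#'
#' @param catalogs a `dn_catalogs`.
#' @return list with named vectors `class` and `name` indexed by canonical key
#'   (class precedence biological > bioactive > chemical).
#' @export
catalog_lookup <- function(catalogs) {
  stopifnot(inherits(catalogs, "dn_catalogs"))
  class_v <- character(0); name_v <- character(0)
  for (cls in c("chemical", "bioactive", "biological")) {   # later wins
    cat <- catalogs[[cls]]
    if (is.null(cat)) next
    class_v[cat$key] <- cls
    name_v[cat$key] <- cat$name
  }
  list(class = class_v, name = name_v)
}

#' Classify a compound by catalog membership
#'
#' Precedence biological > bioactive > chemical when a key occurs in several
#' catalogs (a compound counts once); `"none"` when absent everywhere.
#'
#' @param key a canonical key.
#' @param catalogs a `dn_catalogs`.
#' @return one of `"biological"`, `"bioactive"`, `"chemical"`, `"none"`.
#' @export
classify_compound <- function(key, catalogs) {
  for (cls in c("biological", "bioactive", "chemical")) {
    cat <- catalogs[[cls]]
    if (!is.null(cat) && key %in% cat$key) return(cls)
  }
  "none"
}

#' Popularity of a compound
#'
#' Popularity is defined as the sum of the number of citations and patents
#' reported for the compound.
#'
#' @param citations,patents non-negative integer counts.
#' @return integer sum.
#' @export
popularity <- function(citations, patents) {
  if (any(citations < 0) || any(patents < 0))
    .dn_stop("dn_validation_error", "citation and patent counts must be >= 0")
  as.integer(citations) + as.integer(patents)
}

#' Load a compound annotation table
#'
#' TSV with columns `name`, `citations`, `patents` and optionally
#' `total_printed` (the total as printed in the source table, kept so
#' inconsistent sums can be flagged by [validate_annotations()]).
#'
#' @param path TSV path.
#' @return data frame with computed `popularity` column.
#' @export
load_annotations <- function(path) {
  if (!file.exists(path))
    .dn_stop("dn_config_error", "annotation file '%s' does not exist", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "citations", "patents")
  if (!all(need %in% names(df)))
    .dn_stop("dn_config_error", "annotation table must have columns %s",
             paste(need, collapse = ", "))
  df$popularity <- popularity(df$citations, df$patents)
  df
}

#' Flag annotation rows whose printed total disagrees with the sum
#'
#' The sum of citations and patents is definitional for popularity; source
#' tables occasionally print a total that does not match. This returns the
#' offending rows rather than propagating the printed number.
#'
#' @param annotations a [load_annotations()] table with a `total_printed` column.
#' @return data frame of inconsistent rows (possibly empty).
#' @export
validate_annotations <- function(annotations) {
  if (!"total_printed" %in% names(annotations))
    return(annotations[0, , drop = FALSE])
  bad <- !is.na(annotations$total_printed) &
    annotations$total_printed != annotations$popularity
  annotations[bad, , drop = FALSE]
}

.dn_compound_df <- function(n) {
  data.frame(key = names(n$compounds),
             name = vapply(n$compounds, `[[`, character(1), "name"),
             generation = vapply(n$compounds, `[[`, integer(1), "generation"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank candidate derivatives by popularity
#'
#' Seed metabolites are excluded, compounds without a single annotation
#' (popularity 0) are dropped, and the remainder is sorted by popularity
#' descending with ties broken by compound name ascending. When a reference
#' database and rules are supplied, each row also carries the best enzyme
#' candidate score and predicted EC for the reactions producing the compound.
#'
#' @param network a (typically trimmed) `dn_network`.
#' @param annotations a [load_annotations()] table (joined by compound name;
#'   compounds missing from it count as 0 citations, 0 patents).
#' @param exclude a `dn_pathway` or character vector of canonical keys to
#'   exclude (the seed metabolites).
#' @param reference optional [load_reference_db()] table for enzyme scoring.
#' @param rules optional [load_rules()] collection (needed with `reference`).
#' @param sim_config a [similarity_config()].
#' @return a `data.frame` report: rank, name, popularity, citations, patents,
#'   distance (generations from the seed pathway), and optionally
#'   `best_score` / `predicted_ec`.
#' @export
rank_candidates <- function(network, annotations, exclude = NULL,
                            reference = NULL, rules = NULL,
                            sim_config = similarity_config()) {
  stopifnot(inherits(network, "dn_network"))
  comp <- .dn_compound_df(network)
  excl_keys <- if (inherits(exclude, "dn_pathway"))
    vapply(exclude$metabolites, function(m) m$canonical_key, character(1))
  else as.character(exclude %||% character(0))
  comp <- comp[!comp$key %in% excl_keys, , drop = FALSE]
  idx <- match(comp$name, annotations$name)
  comp$citations <- ifelse(is.na(idx), 0L, annotations$citations[idx])
  comp$patents <- ifelse(is.na(idx), 0L, annotations$patents[idx])
  comp$popularity <- popularity(comp$citations, comp$patents)
  comp <- comp[comp$popularity > 0L, , drop = FALSE]
  comp <- comp[order(-comp$popularity, comp$name), , drop = FALSE]
  comp$rank <- seq_len(nrow(comp))
  if (!is.null(reference) && !is.null(rules) && nrow(comp)) {
    best <- lapply(comp$key, function(k) .dn_best_enzyme_for(network, k, reference,
                                                             rules, sim_config))
    comp$best_score <- vapply(best, function(b) b$score, numeric(1))
    comp$predicted_ec <- vapply(best, function(b) b$ec, character(1))
  }
  rownames(comp) <- NULL
  comp[, c("rank", "name", "popularity", "citations", "patents",
           setdiff(names(comp), c("rank", "name", "popularity", "citations",
                                  "patents", "key")), "key")]
}

.dn_best_enzyme_for <- function(network, key, reference, rules, sim_config) {
  prod_edges <- which(network$edges$product_key == key)
  best <- list(score = NA_real_, ec = NA_character_)
  for (i in prod_edges) {
    e <- network$edges[i, ]
    if (e$status == "known") next
    rxn <- tryCatch(edge_reaction(network, i), error = function(err) NULL)
    if (is.null(rxn)) next
    cand <- rank_enzymes(rxn, reference, config = sim_config)
    if (nrow(cand) && (is.na(best$score) || cand$score[1L] > best$score))
      best <- list(score = cand$score[1L], ec = cand$ec[1L])
  }
  best
}

#' Restrict a candidate report to one-step derivatives
#'
#' Keeps the rows whose compound sits at generation 1 of the network, i.e.
#' one reaction step away from a seed pathway intermediate.
#'
#' @param report a [rank_candidates()] report.
#' @param network the `dn_network` the report was computed from.
#' @param pathway the seed `dn_pathway` (kept for interface completeness; the
#'   generation index already encodes distance from its metabolites).
#' @return the subset report, ranks renumbered.
#' @export
one_step_candidates <- function(report, network, pathway = NULL) {
  gen <- vapply(network$compounds, `[[`, integer(1), "generation")
  keep <- report$key %in% names(gen)[gen == 1L]
  out <- report[keep, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write a candidate report as TSV
#'
#' @param report a [rank_candidates()] report.
#' @param path output path.
#' @param header optional comment lines (config echo) prefixed with `#`.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  df <- report[, setdiff(names(report), "key"), drop = FALSE]
  if ("best_score" %in% names(df)) df$best_score <- sprintf("%.2f", df$best_score)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
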