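# Generation-indexed network expansion restricted to catalogued compounds,
# scaffold trimming, reaction classification, and network export.

#' Expansion configuration
#'
#' @param generations number of expansion iterations (default 4, guard <= 10).
#' @param known_only when `TRUE` (default), rule products absent from the
#'   catalogs are discarded: only known molecular structures enter the network.
#' @return a `dn_expansion_config`.
#' @export
expansion_config <- function(generations = 4L, known_only = TRUE) {
  generations <- as.integer(generations)
  if (is.na(generations) || generations < 0L || generations > 10L)
    .dn_stop("dn_config_error", "generations must be in [0, 10], got %s", generations)
  structure(list(generations = generations, known_only = isTRUE(known_only)),
            class = "dn_expansion_config")
}

.dn_cof_string <- function(x) paste(x, collapse = ",")

.dn_empty_edges <- function() {
  data.frame(substrate_key = character(0), product_key = character(0),
             rule_id = character(0), ec_prefix = character(0),
             direction = character(0), generation = integer(0),
             status = character(0), sub_site = character(0),
             prod_site = character(0),
             cof_fwd_consumes = character(0), cof_fwd_produces = character(0),
             cof_rev_consumes = character(0), cof_rev_produces = character(0),
             stringsAsFactors = FALSE)
}

.dn_seed_mols <- function(seeds) {
  if (inherits(seeds, "dn_pathway")) return(seeds$metabolites)
  if (inherits(seeds, "dn_mol")) return(list(seeds))
  stopifnot(is.list(seeds), all(vapply(seeds, inherits, logical(1), "dn_mol")))
  seeds
}

#' Expand a reaction network around seed metabolites
#'
#' Breadth-first, generation-indexed expansion: at each iteration every rule is
#' applied in both directions to every compound not yet processed; products are
#' canonicalized and deduplicated; when `known_only` is set, products that are
#' neither already in the network nor members of any catalog are discarded.
#' Edges are stored in the rule's forward orientation and deduplicated by
#' (substrate, product, rule). A closing pass records reactions among already
#' retained compounds discovered at the last iteration, without adding nodes.
#'
#' When `seeds` is a pathway definition, its own reactions are marked
#' `known` (the seed pathway counts as known chemistry); everything else is
#' `novel` until annotated against a reference database
#' (see [annotate_network()]).
#'
#' @param seeds a `dn_pathway`, a `dn_mol`, or a list of `dn_mol`.
#' @param rules a [load_rules()] collection.
#' @param catalogs a [load_catalogs()] collection (or `NULL`).
#' @param config an [expansion_config()].
#' @return a `dn_network`: `compounds` (named list keyed by canonical key with
#'   `mol`, `name`, `generation`, `catalog_class`) and `edges` (data frame).
#' @export
expand_network <- function(seeds, rules, catalogs = NULL,
                           config = expansion_config()) {
  stopifnot(inherits(config, "dn_expansion_config"), inherits(rules, "dn_rules"))
  mols <- .dn_seed_mols(seeds)
  if (!length(mols)) .dn_stop("dn_config_error", "no seed metabolites given")
  lookup <- if (!is.null(catalogs)) catalog_lookup(catalogs)
  compounds <- list()
  for (m in mols) {
    k <- m$canonical_key
    if (is.null(compounds[[k]]))
      compounds[[k]] <- list(mol = m, name = m$name, generation = 0L,
                             catalog_class = if (!is.null(lookup)) classify_compound(k, catalogs) else "none")
  }
  edges <- .dn_empty_edges()
  edge_ids <- character(0)
  add_edge <- function(sub_key, prod_key, rule, gen, sub_site, prod_site) {
    id <- paste(sub_key, prod_key, rule$rule_id, sep = "\r")
    if (id %in% edge_ids) return(invisible())
    edge_ids <<- c(edge_ids, id)
    edges[nrow(edges) + 1L, ] <<- list(
      sub_key, prod_key, rule$rule_id, rule$ec_prefix, "forward", gen, "novel",
      paste(sub_site, collapse = ","), paste(prod_site, collapse = ","),
      .dn_cof_string(rule$forward$cofactors$consumes),
      .dn_cof_string(rule$forward$cofactors$produces),
      .dn_cof_string(rule$reverse$cofactors$consumes),
      .dn_cof_string(rule$reverse$cofactors$produces))
  }
  processed <- character(0)
  gens <- config$generations
  for (g in seq_len(max(gens, 0L))) {
    todo <- setdiff(names(compounds), processed)
    final_round <- g == gens
    for (key in todo) {
      processed <- c(processed, key)
      m <- compounds[[key]]$mol
      for (rule in rules) for (dirn in c("forward", "reverse")) {
        outs <- apply_rule(rule, m, dirn)
        for (o in outs) {
          pk <- o$product$canonical_key
          known <- !is.null(compounds[[pk]]) ||
            (!is.null(lookup) && !is.na(lookup$class[pk])) ||
            !config$known_only
          if (!known) next
          is_new <- is.null(compounds[[pk]])
          if (is_new && final_round) next   # closing pass: no new nodes
          if (is_new) {
            nm <- if (!is.null(lookup) && !is.na(lookup$name[pk])) lookup$name[[pk]] else ""
            compounds[[pk]] <- list(mol = o$product, name = nm, generation = g,
                                    catalog_class = if (!is.null(lookup)) classify_compound(pk, catalogs) else "none")
          }
          if (dirn == "forward")
            add_edge(key, pk, rule, g, o$site_atoms, o$product_site)
          else
            add_edge(pk, key, rule, g, o$product_site, o$site_atoms)
        }
      }
    }
  }
  net <- structure(list(compounds = compounds, edges = edges,
                        config = list(generations = gens,
                                      known_only = config$known_only,
                                      rule_set_id = attr(rules, "rule_set_id"))),
                   class = "dn_network")
  if (inherits(seeds, "dn_pathway")) net <- .dn_mark_pathway_known(net, seeds)
  net
}

.dn_pathway_pairs <- function(pathway) {
  mets <- pathway$metabolites
  keyof <- vapply(mets, function(m) m$canonical_key, character(1))
  data.frame(sub = unname(keyof[pathway$reactions$substrate]),
             prod = unname(keyof[pathway$reactions$product]),
             rule_id = pathway$reactions$rule_id, stringsAsFactors = FALSE)
}

.dn_mark_pathway_known <- function(net, pathway) {
  pp <- .dn_pathway_pairs(pathway)
  pair <- paste(net$edges$substrate_key, net$edges$product_key)
  hit <- pair %in% paste(pp$sub, pp$prod) | pair %in% paste(pp$prod, pp$sub)
  net$edges$status[hit] <- "known"
  net
}

#' Classify a reaction edge as known or novel
#'
#' A reaction is known if it is part of the reference reaction database or of
#' the seed pathway; otherwise it is novel. Reference matching compares the
#' (substrate, product, rule) triple in either orientation; seed-pathway
#' matching compares the compound pair under any rule.
#'
#' @param edge a single edge (one-row data frame or list) with `substrate_key`,
#'   `product_key`, `rule_id`.
#' @param reference a [load_reference_db()] table (or `NULL`).
#' @param pathway a `dn_pathway` (or `NULL`).
#' @return `"known"` or `"novel"`.
#' @export
classify_reaction <- function(edge, reference = NULL, pathway = NULL) {
  s <- edge$substrate_key; p <- edge$product_key; r <- edge$rule_id
  if (!is.null(reference) && nrow(reference)) {
    ref <- paste(reference$substrate_key, reference$product_key, reference$rule_id)
    if (paste(s, p, r) %in% ref || paste(p, s, r) %in% ref) return("known")
  }
  if (!is.null(pathway)) {
    pp <- .dn_pathway_pairs(pathway)
    if (paste(s, p) %in% paste(pp$sub, pp$prod) ||
        paste(s, p) %in% paste(pp$prod, pp$sub)) return("known")
  }
  "novel"
}

#' Annotate every network edge with its known/novel status
#'
#' @param n a `dn_network`.
#' @param reference a [load_reference_db()] table.
#' @param pathway the seed `dn_pathway`.
#' @return the network with `edges$status` updated.
#' @export
annotate_network <- function(n, reference = NULL, pathway = NULL) {
  stopifnot(inherits(n, "dn_network"))
  if (nrow(n$edges))
    n$edges$status <- vapply(seq_len(nrow(n$edges)), function(i)
      classify_reaction(n$edges[i, ], reference, pathway), character(1))
  n
}

#' Trim a network to compounds meeting a composition filter
#'
#' Retains exactly the compounds passing the filter, and the edges whose both
#' endpoints are retained. Idempotent.
#'
#' @param n a `dn_network` whose compounds carry structures.
#' @param spec a [bia_filter()].
#' @return the trimmed `dn_network`.
#' @export
trim_network <- function(n, spec = bia_filter()) {
  stopifnot(inherits(n, "dn_network"))
  keep <- vapply(n$compounds, function(cp) passes_filter(cp$mol, spec), logical(1))
  n$compounds <- n$compounds[keep]
  ok <- n$edges$substrate_key %in% names(n$compounds) &
    n$edges$product_key %in% names(n$compounds)
  n$edges <- n$edges[ok, , drop = FALSE]
  rownames(n$edges) <- NULL
  n$config$trimmed <- list(min_c = spec$min_c, min_h = spec$min_h, min_n = spec$min_n)
  n
}

#' @export
print.dn_network <- function(x, ...) {
  gens <- vapply(x$compounds, `[[`, integer(1), "generation")
  cat(sprintf("<Network> %d compounds, %d reactions (%d generations run)\n",
              length(x$compounds), nrow(x$edges), x$config$generations))
  if (length(gens)) print(table(generation = gens))
  invisible(x)
}

# -- export --------------------------------------------------------------------

.dn_network_igraph <- function(n) {
  keys <- names(n$compounds)
  vdf <- data.frame(
    name = keys,
    label = vapply(n$compounds, `[[`, character(1), "name"),
    generation = vapply(n$compounds, `[[`, integer(1), "generation"),
    catalog_class = vapply(n$compounds, function(cp)
      if (is.null(cp$catalog_class) || is.na(cp$catalog_class)) "none" else cp$catalog_class,
      character(1)),
    stringsAsFactors = FALSE)
  edf <- n$edges[, c("substrate_key", "product_key", "rule_id", "status", "generation")]
  names(edf)[1:2] <- c("from", "to")
  igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
}

#' Export a network as GraphML (Gephi-compatible)
#'
#' Vertices carry `label`, `generation` and `catalog_class`; edges carry
#' `rule_id`, `status` and `generation`.
#'
#' @param n a `dn_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(n, path) {
  g <- .dn_network_igraph(n)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a network as JSON
#'
#' Canonical schema: `compounds` (key, name, generation, catalog_class,
#' formula, smiles) and `reactions` (the edge table), plus the expansion
#' config echo.
#'
#' @param n a `dn_network`.
#' @param path output file path.
#' @param smiles include a SMILES rendering of every compound (default TRUE).
#' @return `path`, invisibly.
#' @export
write_network_json <- function(n, path, smiles = TRUE) {
  comp <- data.frame(
    key = names(n$compounds),
    name = vapply(n$compounds, `[[`, character(1), "name"),
    generation = vapply(n$compounds, `[[`, integer(1), "generation"),
    catalog_class = vapply(n$compounds, function(cp)
      if (is.null(cp$catalog_class) || is.na(cp$catalog_class)) "none" else cp$catalog_class,
      character(1)),
    formula = vapply(n$compounds, function(cp) .dn_formula(cp$mol$element_counts),
                     character(1)),
    stringsAsFactors = FALSE)
  if (smiles)
    comp$smiles <- vapply(n$compounds, function(cp) smiles_text(cp$mol), character(1))
  rownames(comp) <- NULL
  jsonlite::write_json(list(config = n$config, compounds = comp, reactions = n$edges),
                       path, dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
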