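# Packaged, download-free fixtures reproducing the study system: the noscapine
# pathway (17 metabolites, 17 reactions, 11 rule classes), compound catalogs,
# the literature annotation table, a mini reference reaction database, and a
# seeded random-network generator for property tests.

.dn_cache <- new.env(parent = emptyenv())

.dn_extdata <- function(file) {
  p <- system.file("extdata", file, package = "derivnet")
  if (!nzchar(p)) p <- file.path("inst", "extdata", file)   # pre-install use
  p
}

#' The packaged generalized reaction rules for the BIA fixture set
#'
#' @return a `dn_rules` collection (see [load_rules()]).
#' @export
bia_rules <- function() {
  if (is.null(.dn_cache$rules))
    .dn_cache$rules <- load_rules(.dn_extdata("rules_bia.yaml"))
  .dn_cache$rules
}

#' The packaged noscapine pathway
#'
#' The seed pathway from norcoclaurine to noscapine: 17 metabolites connected
#' by 17 reactions catalyzed by 11 distinct generalized rule classes (the
#' final steps form a diamond: O-methylation and deacetylation commute on the
#' way to narcotinehemiacetal). Structures are embedded stereo-free; the
#' hemiacetal-series intermediates are carried as their ring-opened aldehyde
#' constitutions so that every step is a single subgraph rewrite.
#'
#' @return a `dn_pathway`: `name`, ordered named list `metabolites` of
#'   `dn_mol`, `reactions` data frame (substrate, product, rule_id, enzyme)
#'   and `rule_classes`.
#' @export
noscapine_pathway <- function() {
  if (!is.null(.dn_cache$pathway)) return(.dn_cache$pathway)
  mets <- utils::read.delim(.dn_extdata("pathway_noscapine_metabolites.tsv"),
                            stringsAsFactors = FALSE)
  mets <- mets[order(mets$order), ]
  mols <- lapply(seq_len(nrow(mets)), function(i)
    parse_structure(mets$smiles[i], "smiles", name = mets$name[i]))
  names(mols) <- mets$name
  rxns <- utils::read.delim(.dn_extdata("pathway_noscapine_reactions.tsv"),
                            stringsAsFactors = FALSE)
  stopifnot(all(rxns$substrate %in% mets$name), all(rxns$product %in% mets$name))
  pw <- structure(list(name = "noscapine", metabolites = mols, reactions = rxns,
                       rule_classes = sort(unique(rxns$rule_id))),
                  class = "dn_pathway")
  .dn_cache$pathway <- pw
  pw
}

#' @export
print.dn_pathway <- function(x, ...) {
  cat(sprintf("<PathwayDefinition> %s: %d metabolites, %d reactions, %d rule classes\n",
              x$name, length(x$metabolites), nrow(x$reactions),
              length(x$rule_classes)))
  invisible(x)
}

#' The packaged compound catalogs
#'
#' Biological, bioactive and chemical membership tables covering the fixture
#' compounds and the derivative targets (tetrahydropalmatine, armepavine,
#' laudanine, nandinine, berberine, columbamine, ...). Identifiers are
#' synthetic.
#'
#' @return a `dn_catalogs` (see [load_catalogs()]).
#' @export
mini_catalogs <- function() {
  if (is.null(.dn_cache$catalogs))
    .dn_cache$catalogs <- load_catalogs(c(
      biological = .dn_extdata("catalog_biological.tsv"),
      bioactive = .dn_extdata("catalog_bioactive.tsv"),
      chemical = .dn_extdata("catalog_chemical.tsv")))
  .dn_cache$catalogs
}

#' The packaged literature annotation table
#'
#' Citation and patent counts for the 15 one-step candidate compounds, as
#' printed in the source table; `total_printed` preserves the printed totals
#' so that [validate_annotations()] can flag rows whose printed sum is
#' inconsistent (popularity itself is always recomputed as
#' citations + patents).
#'
#' @return a [load_annotations()] data frame.
#' @export
annotation_table <- function() {
  if (is.null(.dn_cache$annotations))
    .dn_cache$annotations <- load_annotations(.dn_extdata("annotations_table1.tsv"))
  .dn_cache$annotations
}

#' The packaged mini reference reaction database
#'
#' 25 gene-annotation-flagged reference reactions covering the enzyme classes
#' relevant to the fixture derivatizations (aromatic O-methyltransferases on
#' BIA and non-BIA substrates, N-methyltransferase, methylenedioxy-bridge
#' P450s, berberine bridge enzyme, tetrahydroprotoberberine oxidase, aromatic
#' hydroxylase), including one orphan entry without sequence annotation.
#' Some non-BIA native substrates are embedded as simplified synthetic
#' surrogate structures (marked in `native_substrate`).
#'
#' @return a [load_reference_db()] table.
#' @export
mini_reference_db <- function() {
  if (is.null(.dn_cache$refdb))
    .dn_cache$refdb <- load_reference_db(.dn_extdata("reference_reactions.tsv"),
                                         bia_rules())
  .dn_cache$refdb
}

#' Seeded random network generator
#'
#' Builds an abstract generation-indexed network (no structures) for
#' property-style tests of the pathway search: a random arborescence from the
#' seed compounds guarantees the generation invariant, plus extra random
#' edges. Reproducible per seed; the global RNG state is restored on exit.
#'
#' @param seed integer seed.
#' @param n_nodes total number of compounds (>= n_seeds + 1).
#' @param n_edges total number of reactions (>= n_nodes - n_seeds; capped by
#'   the number of distinct ordered pairs).
#' @param n_seeds number of generation-0 seed compounds.
#' @param p_excluded probability that an edge's reverse direction produces O2
#'   (so its reverse arc is excluded under default search exclusions).
#' @return a `dn_network` whose compounds carry no structures (`mol = NULL`).
#' @export
random_network <- function(seed, n_nodes = 10L, n_edges = 15L, n_seeds = 2L,
                           p_excluded = 0) {
  n_nodes <- as.integer(n_nodes); n_edges <- as.integer(n_edges)
  n_seeds <- as.integer(n_seeds)
  if (n_nodes < n_seeds + 1L || n_nodes > 200L || n_seeds < 1L)
    .dn_stop("dn_config_error", "infeasible random network sizes")
  if (n_edges < n_nodes - n_seeds || n_edges > n_nodes * (n_nodes - 1L))
    .dn_stop("dn_config_error", "n_edges must be in [n_nodes - n_seeds, n*(n-1)]")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  keys <- sprintf("cpd%03d", seq_len(n_nodes))
  gen <- integer(n_nodes); gen[seq_len(n_seeds)] <- 0L
  edges <- .dn_empty_edges()
  seen <- character(0)
  put <- function(a, b, g) {
    id <- paste(a, b)
    if (id %in% seen || a == b) return(FALSE)
    seen <<- c(seen, id)
    excl <- stats::runif(1) < p_excluded
    edges[nrow(edges) + 1L, ] <<- list(
      keys[a], keys[b], sample(c("r1", "r2"), 1L), "-.-.-.-", "forward",
      max(g, 1L), "novel", "1", "1", "", "", "", if (excl) "O2" else "")
    TRUE
  }
  for (i in (n_seeds + 1L):n_nodes) {
    parent <- sample.int(i - 1L, 1L)
    gen[i] <- gen[parent] + 1L
    put(parent, i, gen[i])
  }
  tries <- 0L
  while (nrow(edges) < n_edges && tries < 50L * n_edges) {
    tries <- tries + 1L
    a <- sample.int(n_nodes, 1L); b <- sample.int(n_nodes, 1L)
    put(a, b, max(gen[a] + 1L, 1L))
  }
  # extra edges can shorten routes: recompute generations as BFS distance from
  # the seeds so the network invariant (gen = 1 + min substrate gen) holds
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- match(edges$substrate_key[k], keys); b <- match(edges$product_key[k], keys)
      if (b > n_seeds && gen[a] + 1L < gen[b]) { gen[b] <- gen[a] + 1L; changed <- TRUE }
    }
    if (!changed) break
  }
  edges$generation <- pmax(1L, gen[match(edges$product_key, keys)])
  compounds <- lapply(seq_len(n_nodes), function(i)
    list(mol = NULL, name = keys[i], generation = gen[i], catalog_class = "none"))
  names(compounds) <- keys
  structure(list(compounds = compounds, edges = edges,
                 config = list(generations = max(gen), known_only = FALSE,
                               rule_set_id = sprintf("random(seed=%d)", seed))),
            class = "dn_network")
}
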