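# Reactive-site-centred reaction fingerprints, bounded similarity scoring,
# enzyme candidate ranking and the pathway feasibility metric.
#
# The fingerprint is this package's own construction satisfying the published
# contracts: features are canonical atom-environment descriptors at bond radii
# 1..max_depth around the reactive-site atoms of both reaction sides; the
# score is the unweighted mean over depths of the Jaccard overlap of the
# per-depth feature sets, hence in [0, 1], symmetric, and 1.0 exactly when the
# two reactions are indistinguishable within max_depth bonds of their sites.

#' Similarity configuration
#'
#' @param max_depth neighbourhood radius in bonds around the reactive site
#'   (default 7, the maximal depth; guard 1..7).
#' @param threshold significance threshold on the score (default 0.3; scores
#'   strictly above it count as significant).
#' @return a `dn_similarity_config`.
#' @export
similarity_config <- function(max_depth = 7L, threshold = 0.3) {
  max_depth <- as.integer(max_depth)
  if (is.na(max_depth) || max_depth < 1L || max_depth > 7L)
    .dn_stop("dn_config_error", "max_depth must be in [1, 7]")
  if (threshold < 0 || threshold > 1)
    .dn_stop("dn_config_error", "threshold must be in [0, 1]")
  structure(list(max_depth = max_depth, threshold = threshold),
            class = "dn_similarity_config")
}

#' Construct a reaction from substrate, product and rule
#'
#' Re-matches the rule against the substrate and selects the match that yields
#' the given product, thereby locating the reactive-site atoms on both sides.
#'
#' @param substrate,product `dn_mol` structures.
#' @param rule a rule from a [load_rules()] collection.
#' @param direction rule direction that turns substrate into product.
#' @return a `dn_reaction`: substrate, product, rule_id, `sub_site` and
#'   `prod_site` atom index vectors.
#' @export
as_reaction <- function(substrate, product, rule,
                        direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  outs <- apply_rule(rule, substrate, direction)
  for (o in outs) {
    if (o$product$canonical_key == product$canonical_key)
      return(structure(list(substrate = substrate, product = o$product,
                            rule_id = rule$rule_id, direction = direction,
                            sub_site = o$site_atoms, prod_site = o$product_site),
                       class = "dn_reaction"))
  }
  .dn_stop("dn_consistency_error",
           "rule '%s' (%s) does not transform '%s' into '%s'",
           rule$rule_id, direction, substrate$name, product$name)
}

#' Reaction view of a network edge
#'
#' Edges store the reactive-site atoms recorded at rule application time;
#' this resolves the endpoint structures and wraps them as a `dn_reaction`.
#'
#' @param n a `dn_network`.
#' @param i edge row index.
#' @return a `dn_reaction`.
#' @export
edge_reaction <- function(n, i) {
  e <- n$edges[i, ]
  sub <- n$compounds[[e$substrate_key]]; prod <- n$compounds[[e$product_key]]
  if (is.null(sub$mol) || is.null(prod$mol))
    .dn_stop("dn_consistency_error", "edge endpoints lack structures")
  structure(list(substrate = sub$mol, product = prod$mol, rule_id = e$rule_id,
                 direction = "forward",
                 sub_site = as.integer(strsplit(e$sub_site, ",")[[1L]]),
                 prod_site = as.integer(strsplit(e$prod_site, ",")[[1L]])),
            class = "dn_reaction")
}

#' Reactive-site atoms of a reaction
#'
#' @param rxn a `dn_reaction`.
#' @return list with `substrate` and `product` atom index vectors.
#' @export
reactive_site <- function(rxn) {
  stopifnot(inherits(rxn, "dn_reaction"))
  list(substrate = rxn$sub_site, product = rxn$prod_site)
}

.dn_atom_label <- function(mol, i) {
  a <- mol$atoms
  paste0(a$elem[i], if (a$charge[i] != 0L) sprintf("%+d", a$charge[i]) else "",
         if (a$arom[i]) "a" else "", "H", a$nh[i])
}

.dn_bond_dists <- function(mol, from) {
  # BFS bond distances from one atom
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    adj[[mol$bonds$a1[k]]] <- c(adj[[mol$bonds$a1[k]]], mol$bonds$a2[k])
    adj[[mol$bonds$a2[k]]] <- c(adj[[mol$bonds$a2[k]]], mol$bonds$a1[k])
  }
  d <- rep(NA_integer_, n); d[from] <- 0L
  q <- from
  while (length(q)) {
    v <- q[1L]; q <- q[-1L]
    for (nb in adj[[v]]) if (is.na(d[nb])) { d[nb] <- d[v] + 1L; q <- c(q, nb) }
  }
  d
}

.dn_side_features <- function(mol, site, side, max_depth) {
  labs <- vapply(seq_len(nrow(mol$atoms)), function(i) .dn_atom_label(mol, i),
                 character(1))
  feats <- vector("list", max_depth)
  for (a in sort(site)) {
    d <- .dn_bond_dists(mol, a)
    for (depth in seq_len(max_depth)) {
      inball <- which(!is.na(d) & d <= depth - 1L & d > 0L)
      env <- paste0(side, ":", depth, ":", labs[a], "{",
                    paste(sort(paste0(d[inball], "-", labs[inball])), collapse = ","),
                    "}")
      feats[[depth]] <- c(feats[[depth]], env)
    }
  }
  lapply(feats, function(f) sort(unique(f)))
}

#' Reactive-site-centred reaction fingerprint
#'
#' Per-depth feature sets for depths 1..`max_depth`. The depth-d feature of a
#' reactive-site atom is the string
#' `"<side>:<d>:<label>{<dist>-<label>,...}"` where `side` is `S`
#' (substrate) or `P` (product), `label` encodes element, formal charge,
#' aromaticity flag and implicit hydrogen count (e.g. `CaH1`, `O-1H0`), and
#' the braces hold the sorted labels of all atoms up to `d - 1` bonds from the
#' site atom with their bond distance. Depth 1 is therefore the reactive-site
#' atoms themselves ("up to seven atoms around the site" is read as shells of
#' growing bond radius), and depth-d features depend only on atoms within
#' d bonds of the site.
#'
#' @param rxn a `dn_reaction`.
#' @param config a [similarity_config()].
#' @return a `dn_fingerprint`: list of per-depth feature sets.
#' @export
reaction_fingerprint <- function(rxn, config = similarity_config()) {
  stopifnot(inherits(rxn, "dn_reaction"), inherits(config, "dn_similarity_config"))
  if (!length(rxn$sub_site))
    .dn_stop("dn_consistency_error", "reaction has an empty reactive site")
  sub <- .dn_side_features(rxn$substrate, rxn$sub_site, "S", config$max_depth)
  prod <- .dn_side_features(rxn$product, rxn$prod_site, "P", config$max_depth)
  levels <- lapply(seq_len(config$max_depth), function(d) sort(c(sub[[d]], prod[[d]])))
  structure(list(levels = levels, max_depth = config$max_depth),
            class = "dn_fingerprint")
}

#' Similarity between two reaction fingerprints
#'
#' Unweighted mean over depths of the Jaccard overlap of the per-depth feature
#' sets (so deeper shells are weighted no higher than shallower ones).
#' Symmetric, bounded in [0, 1]; 1.0 iff the fingerprints are identical, 0
#' when no features are shared.
#'
#' @param a,b `dn_fingerprint` objects built with the same `max_depth`.
#' @return numeric score in [0, 1].
#' @export
reaction_similarity <- function(a, b) {
  stopifnot(inherits(a, "dn_fingerprint"), inherits(b, "dn_fingerprint"))
  if (a$max_depth != b$max_depth)
    .dn_stop("dn_config_error", "fingerprints built with different max_depth")
  j <- vapply(seq_len(a$max_depth), function(d) {
    fa <- a$levels[[d]]; fb <- b$levels[[d]]
    if (!length(fa) && !length(fb)) return(1)
    u <- length(union(fa, fb))
    if (u == 0L) 1 else length(intersect(fa, fb)) / u
  }, numeric(1))
  mean(j)
}

#' Load a reference reaction database
#'
#' TSV columns: `reaction_id`, `ec`, `native_substrate`, `substrate_type`,
#' `organism`, `has_sequence`, `rule_id`, `substrate_smiles`,
#' `product_smiles`. Structures are parsed, canonical keys computed, and each
#' entry is checked for consistency: the named rule applied to the substrate
#' must yield the stored product (this also locates the reactive site).
#'
#' @param path TSV path.
#' @param rules a [load_rules()] collection.
#' @return data frame with `substrate_key`/`product_key` columns and a
#'   `reactions` attribute holding the `dn_reaction` per row.
#' @export
load_reference_db <- function(path, rules) {
  if (!file.exists(path))
    .dn_stop("dn_config_error", "reference database '%s' does not exist", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("reaction_id", "ec", "native_substrate", "substrate_type", "organism",
            "has_sequence", "rule_id", "substrate_smiles", "product_smiles")
  if (!all(need %in% names(df)))
    .dn_stop("dn_config_error", "reference db must have columns %s",
             paste(need, collapse = ", "))
  ok_ec <- grepl("^\\d+\\.(\\d+|-)\\.(\\d+|-)\\.(\\d+|-)$", df$ec)
  if (!all(ok_ec))
    .dn_stop("dn_config_error", "malformed EC '%s' in reference db",
             df$ec[!ok_ec][1L])
  df$has_sequence <- as.logical(df$has_sequence)
  rxns <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    sub <- parse_structure(df$substrate_smiles[i], "smiles",
                           name = df$native_substrate[i])
    prod <- parse_structure(df$product_smiles[i], "smiles")
    rule <- rules[[df$rule_id[i]]]
    if (is.null(rule))
      .dn_stop("dn_config_error", "reference entry '%s' names unknown rule '%s'",
               df$reaction_id[i], df$rule_id[i])
    rxns[[i]] <- as_reaction(sub, prod, rule)
    df$substrate_key[i] <- sub$canonical_key
    df$product_key[i] <- prod$canonical_key
  }
  attr(df, "reactions") <- setNames(rxns, df$reaction_id)
  df
}

#' Rank enzyme candidates for a novel reaction
#'
#' Scores the reaction against every gene-annotated entry of the reference
#' database (entries without sequence annotation are removed), sorts by score
#' descending with ties broken by EC ascending, and keeps the single best row
#' per EC class.
#'
#' @param rxn a `dn_reaction` (the novel reaction).
#' @param reference a [load_reference_db()] table.
#' @param config a [similarity_config()].
#' @return data frame: rank, score, ec, native_substrate, substrate_type,
#'   organism, reference_id. Empty (with a warning) if no entry carries a
#'   sequence annotation.
#' @export
rank_enzymes <- function(rxn, reference, config = similarity_config()) {
  stopifnot(inherits(rxn, "dn_reaction"))
  if (!nrow(reference)) .dn_stop("dn_config_error", "reference database is empty")
  keep <- which(reference$has_sequence)
  if (!length(keep)) {
    warning("no gene-annotated reference reactions; empty candidate list")
    return(data.frame(rank = integer(0), score = numeric(0), ec = character(0),
                      native_substrate = character(0), substrate_type = character(0),
                      organism = character(0), reference_id = character(0)))
  }
  fp <- reaction_fingerprint(rxn, config)
  refs <- attr(reference, "reactions")
  scores <- vapply(keep, function(i)
    reaction_similarity(fp, reaction_fingerprint(refs[[reference$reaction_id[i]]],
                                                 config)),
    numeric(1))
  cand <- data.frame(score = scores, ec = reference$ec[keep],
                     native_substrate = reference$native_substrate[keep],
                     substrate_type = reference$substrate_type[keep],
                     organism = reference$organism[keep],
                     reference_id = reference$reaction_id[keep],
                     stringsAsFactors = FALSE)
  cand <- cand[order(-cand$score, cand$ec, cand$reference_id), , drop = FALSE]
  cand <- cand[!duplicated(cand$ec), , drop = FALSE]   # best row per EC class
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  cand[, c("rank", "score", "ec", "native_substrate", "substrate_type",
           "organism", "reference_id")]
}

#' Filter enzyme candidates by significance
#'
#' Keeps candidates whose score is strictly above the configured threshold.
#'
#' @param candidates a [rank_enzymes()] table.
#' @param config a [similarity_config()].
#' @return the filtered table.
#' @export
significant_candidates <- function(candidates, config = similarity_config()) {
  out <- candidates[candidates$score > config$threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enzymatic feasibility of a pathway
#'
#' For each reaction step the top enzyme candidate score is taken (steps whose
#' network reaction is already known score 1.0: an enzyme is assigned);
#' the pathway metric is the arithmetic mean of these per-step top scores.
#'
#' @param p a `dn_path` from [enumerate_pathways()].
#' @param n the `dn_network` the pathway was extracted from.
#' @param reference a [load_reference_db()] table.
#' @param config a [similarity_config()].
#' @return a `dn_pathway_score`: `step_scores` and `mean_top_score`.
#' @export
pathway_feasibility <- function(p, n, reference, config = similarity_config()) {
  stopifnot(inherits(p, "dn_path"))
  if (!p$length) .dn_stop("dn_config_error", "empty pathway cannot be scored")
  step_scores <- vapply(seq_len(p$length), function(i) {
    ei <- p$steps$edge_index[i]
    if (n$edges$status[ei] == "known") return(1.0)
    rxn <- edge_reaction(n, ei)
    cand <- rank_enzymes(rxn, reference, config)
    if (!nrow(cand)) 0.0 else cand$score[1L]
  }, numeric(1))
  structure(list(step_scores = step_scores,
                 mean_top_score = mean(step_scores)),
            class = "dn_pathway_score")
}

#' @export
print.dn_pathway_score <- function(x, ...) {
  cat(sprintf("<PathwayScore> mean of per-step top scores: %.3f (%s)\n",
              x$mean_top_score, paste(sprintf("%.2f", x$step_scores),
                                      collapse = ", ")))
  invisible(x)
}
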