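# Directed reactant-product graph with directionality exclusions, and
# enumeration of linear pathways within a step cap.

#' Pathway search configuration
#'
#' @param max_steps maximal number of reaction steps in a pathway
#'   (default 4, guard <= 8).
#' @param exclusions directionality exclusions applied when building the
#'   reactant-product graph; any subset of `produces_O2` (the travelled
#'   direction releases molecular oxygen), `fixes_CO2_reverse_decarboxylation`
#'   (binds carbon dioxide to the substrate) and `demethylation_SAH_to_SAM`
#'   (a demethylation regenerating S-adenosylmethionine from
#'   S-adenosylhomocysteine). All three by default.
#' @return a `dn_search_config`.
#' @export
search_config <- function(max_steps = 4L,
                          exclusions = c("produces_O2",
                                         "fixes_CO2_reverse_decarboxylation",
                                         "demethylation_SAH_to_SAM")) {
  max_steps <- as.integer(max_steps)
  if (is.na(max_steps) || max_steps < 1L || max_steps > 8L)
    .dn_stop("dn_config_error", "max_steps must be in [1, 8]")
  known <- c("produces_O2", "fixes_CO2_reverse_decarboxylation",
             "demethylation_SAH_to_SAM")
  exclusions <- as.character(exclusions)
  if (!all(exclusions %in% known))
    .dn_stop("dn_config_error", "unknown exclusion '%s'",
             setdiff(exclusions, known)[1L])
  structure(list(max_steps = max_steps, exclusions = exclusions),
            class = "dn_search_config")
}

#' Is a travelled reaction direction excluded from the pathway search?
#'
#' @param cofactors cofactor context of the travelled direction: a list with
#'   `consumes` and `produces` character vectors of cofactor names.
#' @param exclusions exclusion set (see [search_config()]).
#' @return `TRUE` iff the direction produces molecular oxygen, binds CO2 to
#'   the substrate, or converts SAH to SAM (demethylation).
#' @export
is_excluded_direction <- function(cofactors,
                                  exclusions = search_config()$exclusions) {
  consumes <- cofactors$consumes %||% character(0)
  produces <- cofactors$produces %||% character(0)
  ("produces_O2" %in% exclusions && "O2" %in% produces) ||
    ("fixes_CO2_reverse_decarboxylation" %in% exclusions && "CO2" %in% consumes) ||
    ("demethylation_SAH_to_SAM" %in% exclusions &&
       "SAM" %in% produces && "SAH" %in% consumes)
}

.dn_cof_parse <- function(s) {
  if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, ",", fixed = TRUE)[[1L]]
}

#' Build the directed reactant-product graph of a network
#'
#' Every network reaction yields up to two arcs, one per travelled direction;
#' directions matching the configured exclusions are absent. Arcs carry the
#' rule id and a deterministic arc id.
#'
#' @param n a `dn_network`.
#' @param config a [search_config()].
#' @return a `dn_pairgraph`: data frame with columns `from`, `to`, `rule_id`,
#'   `travelled`, `arc_id`, plus a `vertices` attribute.
#' @export
build_pair_graph <- function(n, config = search_config()) {
  stopifnot(inherits(n, "dn_network"), inherits(config, "dn_search_config"))
  e <- n$edges
  arcs <- list()
  for (i in seq_len(nrow(e))) {
    fwd <- list(consumes = .dn_cof_parse(e$cof_fwd_consumes[i]),
                produces = .dn_cof_parse(e$cof_fwd_produces[i]))
    rev <- list(consumes = .dn_cof_parse(e$cof_rev_consumes[i]),
                produces = .dn_cof_parse(e$cof_rev_produces[i]))
    if (!is_excluded_direction(fwd, config$exclusions))
      arcs[[length(arcs) + 1L]] <- data.frame(
        from = e$substrate_key[i], to = e$product_key[i], rule_id = e$rule_id[i],
        travelled = "forward", edge_index = i, stringsAsFactors = FALSE)
    if (!is_excluded_direction(rev, config$exclusions))
      arcs[[length(arcs) + 1L]] <- data.frame(
        from = e$product_key[i], to = e$substrate_key[i], rule_id = e$rule_id[i],
        travelled = "reverse", edge_index = i, stringsAsFactors = FALSE)
  }
  g <- if (length(arcs)) do.call(rbind, arcs) else
    data.frame(from = character(0), to = character(0), rule_id = character(0),
               travelled = character(0), edge_index = integer(0))
  g$arc_id <- paste(g$from, g$to, g$rule_id, g$travelled, sep = "|")
  attr(g, "vertices") <- names(n$compounds)
  class(g) <- c("dn_pairgraph", "data.frame")
  g
}

#' Enumerate linear pathways from seed intermediates to a target
#'
#' Returns every simple (vertex-disjoint) directed path of length 1 to
#' `max_steps` arcs from any source to the target. Pathways differing only in
#' the rule assigned to an identical compound chain are kept distinct. Output
#' order is deterministic: by length, then lexicographically on arc ids.
#'
#' @param graph a [build_pair_graph()] result.
#' @param sources character vector of source keys (seed intermediates).
#' @param target target compound key.
#' @param config a [search_config()].
#' @return list of `dn_path` objects (`source`, `target`, `steps` data frame,
#'   `length`); empty (with a warning) when the target is absent from the
#'   graph.
#' @export
enumerate_pathways <- function(graph, sources, target,
                               config = search_config()) {
  stopifnot(inherits(graph, "dn_pairgraph"))
  verts <- attr(graph, "vertices") %||% unique(c(graph$from, graph$to))
  if (!target %in% verts) {
    warning("target compound is not part of the graph")
    return(list())
  }
  sources <- intersect(unique(sources), verts)
  out_arcs <- split(seq_len(nrow(graph)), graph$from)
  results <- list()
  walk <- function(at, visited, arc_rows) {
    if (length(arc_rows) >= config$max_steps) return(invisible())
    for (ai in out_arcs[[at]] %||% integer(0)) {
      nxt <- graph$to[ai]
      if (nxt %in% visited) next
      rows <- c(arc_rows, ai)
      if (nxt == target) {
        results[[length(results) + 1L]] <<- rows
      } else {
        walk(nxt, c(visited, nxt), rows)
      }
    }
  }
  for (s in sources) {
    if (s == target) next   # zero-length pathways are not returned
    walk(s, s, integer(0))
  }
  paths <- lapply(results, function(rows) {
    steps <- graph[rows, , drop = FALSE]
    rownames(steps) <- NULL
    structure(list(source = steps$from[1L], target = target, steps = steps,
                   length = nrow(steps)), class = "dn_path")
  })
  keyfun <- vapply(paths, function(p)
    sprintf("%02d|%s", p$length, paste(p$steps$arc_id, collapse = ">")), character(1))
  paths[order(keyfun)]
}

#' @export
print.dn_path <- function(x, ...) {
  cat(sprintf("<Pathway> %d step(s)\n", x$length))
  for (i in seq_len(nrow(x$steps)))
    cat(sprintf("  %s -[%s/%s]-> %s\n",
                substr(x$steps$from[i], 1L, 16L), x$steps$rule_id[i],
                x$steps$travelled[i], substr(x$steps$to[i], 1L, 16L)))
  invisible(x)
}

#' Is a reference biosynthesis pathway contained in a network?
#'
#' `TRUE` iff every consecutive compound pair of the reference is connected by
#' a network reaction (any rule, either orientation).
#'
#' @param n a `dn_network`.
#' @param reference ordered compounds: a character vector of canonical keys or
#'   a list of `dn_mol` (at least 2 entries).
#' @return logical.
#' @export
contains_pathway <- function(n, reference) {
  stopifnot(inherits(n, "dn_network"))
  keys <- if (is.character(reference)) reference else
    vapply(reference, function(m) m$canonical_key, character(1))
  if (length(keys) < 2L)
    .dn_stop("dn_config_error", "reference pathway needs at least 2 compounds")
  pair <- paste(n$edges$substrate_key, n$edges$product_key)
  for (i in seq_len(length(keys) - 1L)) {
    if (!(paste(keys[i], keys[i + 1L]) %in% pair ||
          paste(keys[i + 1L], keys[i]) %in% pair)) return(FALSE)
  }
  TRUE
}

#' Export a pathway list as TSV (one row per step)
#'
#' @param paths list of `dn_path`.
#' @param path output path.
#' @param labels optional named vector mapping keys to display names.
#' @param header optional comment lines prefixed with `#`.
#' @return `path`, invisibly.
#' @export
write_pathways_tsv <- function(paths, path, labels = NULL, header = character(0)) {
  rows <- list()
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    st <- p$steps
    lab <- function(k) if (!is.null(labels) && k %in% names(labels)) labels[[k]] else k
    rows[[i]] <- data.frame(pathway = i, step = seq_len(nrow(st)),
                            substrate = vapply(st$from, lab, character(1)),
                            product = vapply(st$to, lab, character(1)),
                            rule_id = st$rule_id, travelled = st$travelled,
                            stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pathway = integer(0), step = integer(0), substrate = character(0),
               product = character(0), rule_id = character(0),
               travelled = character(0))
  con <- file(path, "w"); on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
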