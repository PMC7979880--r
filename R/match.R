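# Subgraph pattern matching and rule application (the rewrite engine).
#
# Matching is plain backtracking over heavy atoms; patterns are small (<= 8
# atoms) and molecules fixture-sized, so no indexing is needed. Matches are
# enumerated in atom-index order, which makes rule application fully
# deterministic. Disconnected pattern components are allowed (ring-forming
# rules anchor two separate motifs of one molecule).

.dn_heavy_degree <- function(mol) {
  d <- integer(nrow(mol$atoms))
  if (nrow(mol$bonds)) {
    t1 <- table(factor(mol$bonds$a1, levels = seq_len(nrow(mol$atoms))))
    t2 <- table(factor(mol$bonds$a2, levels = seq_len(nrow(mol$atoms))))
    d <- as.integer(t1 + t2)
  }
  d
}

.dn_atom_ok <- function(mol, deg, ai, pa) {
  a <- mol$atoms
  if (pa$elem != "*" && a$elem[ai] != pa$elem) return(FALSE)
  if (!is.na(pa$arom) && a$arom[ai] != pa$arom) return(FALSE)
  if (a$nh[ai] < pa$min_h) return(FALSE)
  if (!is.na(pa$max_h) && a$nh[ai] > pa$max_h) return(FALSE)
  if (!is.na(pa$charge) && a$charge[ai] != pa$charge) return(FALSE)
  if (!is.na(pa$min_deg) && deg[ai] < pa$min_deg) return(FALSE)
  if (!is.na(pa$max_deg) && deg[ai] > pa$max_deg) return(FALSE)
  TRUE
}

.dn_bond_ok <- function(mol, bi, spec) {
  b <- mol$bonds
  switch(spec,
         "any" = TRUE,
         "ar"  = b$arom[bi],
         "-"   = !b$arom[bi] && !is.na(b$order[bi]) && b$order[bi] == 1L,
         { o <- suppressWarnings(as.integer(spec))
           !is.na(b$order[bi]) && b$order[bi] == o })
}

.dn_find_bond <- function(mol, i, j) {
  which((mol$bonds$a1 == i & mol$bonds$a2 == j) |
        (mol$bonds$a1 == j & mol$bonds$a2 == i))
}

# Returns a list of integer vectors; element k of a vector is the molecule
# atom index mapped to pattern atom k.
.dn_match_pattern <- function(pattern, mol) {
  np <- length(pattern$atoms)
  deg <- .dn_heavy_degree(mol)
  # adjacency of pattern bonds to earlier atoms drives the search order;
  # pattern atoms are taken in declaration order (authors write them DFS-style)
  pb_for <- function(k) Filter(function(pb) (pb$a == k && pb$b < k) || (pb$b == k && pb$a < k),
                               pattern$bonds)
  results <- list()
  assign_next <- function(k, mapping) {
    if (k > np) { results[[length(results) + 1L]] <<- mapping; return(invisible()) }
    back <- pb_for(k)
    for (ai in seq_len(nrow(mol$atoms))) {
      if (ai %in% mapping) next
      if (!.dn_atom_ok(mol, deg, ai, pattern$atoms[[k]])) next
      ok <- TRUE
      for (pb in back) {
        other <- mapping[if (pb$a == k) pb$b else pb$a]
        bi <- .dn_find_bond(mol, ai, other)
        if (!length(bi) || !.dn_bond_ok(mol, bi[1L], pb$order)) { ok <- FALSE; break }
      }
      if (ok) assign_next(k + 1L, c(mapping, ai))
    }
  }
  assign_next(1L, integer(0))
  # bonds between later-declared atom pairs (both already mapped) were checked
  # only when the later atom was placed against earlier ones; verify any bond
  # whose atoms were mapped independently (disconnected declarations)
  ok <- vapply(results, function(mp) {
    for (pb in pattern$bonds) {
      bi <- .dn_find_bond(mol, mp[pb$a], mp[pb$b])
      if (!length(bi) || !.dn_bond_ok(mol, bi[1L], pb$order)) return(FALSE)
    }
    TRUE
  }, logical(1))
  results[ok]
}

# Apply an edit script to a copy of the molecule graph. `mapping` maps pattern
# ids to atom indices. Returns list(atoms, bonds, trace) where trace maps
# pattern/new ids to indices in the edited graph, or NULL when the edit is
# chemically impossible (valence violation).
.dn_apply_edits <- function(mol, pattern_ids, mapping, edits, name = "") {
  atoms <- mol$atoms[, c("elem", "charge"), drop = FALSE]
  bonds <- mol$bonds[, c("a1", "a2", "order"), drop = FALSE]
  idx <- setNames(as.list(mapping), pattern_ids)
  to_delete <- integer(0)
  for (e in edits) {
    if (e$op == "add_atom") {
      atoms <- rbind(atoms, data.frame(elem = e$elem, charge = e$charge))
      idx[[e$id]] <- nrow(atoms)
    } else if (e$op == "add_bond") {
      a <- idx[[e$a]]; b <- idx[[e$b]]
      if (length(.dn_find_bond(list(bonds = bonds), a, b))) return(NULL)
      bonds <- rbind(bonds, data.frame(a1 = a, a2 = b, order = e$order))
    } else if (e$op == "set_bond") {
      bi <- .dn_find_bond(list(bonds = bonds), idx[[e$a]], idx[[e$b]])
      if (!length(bi)) return(NULL)
      bonds$order[bi[1L]] <- e$order
    } else if (e$op == "del_bond") {
      bi <- .dn_find_bond(list(bonds = bonds), idx[[e$a]], idx[[e$b]])
      if (!length(bi)) return(NULL)
      bonds <- bonds[-bi[1L], , drop = FALSE]
    } else if (e$op == "set_charge") {
      atoms$charge[idx[[e$a]]] <- e$charge
    } else if (e$op == "del_atom") {
      to_delete <- c(to_delete, idx[[e$a]])
    }
  }
  if (length(to_delete)) {
    keep <- setdiff(seq_len(nrow(atoms)), to_delete)
    drop_b <- bonds$a1 %in% to_delete | bonds$a2 %in% to_delete
    bonds <- bonds[!drop_b, , drop = FALSE]
    remap <- match(seq_len(nrow(atoms)), keep)
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
    atoms <- atoms[keep, , drop = FALSE]
    idx <- lapply(idx, function(i) { r <- remap[i]; if (is.na(r)) NULL else r })
  }
  rownames(atoms) <- NULL; rownames(bonds) <- NULL
  atoms$arom <- FALSE; atoms$nh <- 0L
  bonds$arom <- FALSE
  m <- tryCatch(dn_mol(atoms, bonds, name = name), dn_chemistry_error = function(e) NULL,
                dn_parse_error = function(e) NULL)
  if (is.null(m)) return(NULL)
  list(mol = m, trace = idx)
}

#' Apply a reaction rule to a molecule
#'
#' Enumerates all matches of the rule's reactive-site pattern in the given
#' direction, applies the rewrite at each site, canonicalizes the products and
#' deduplicates them by canonical key. Matches whose rewrite is chemically
#' impossible (valence violation) or whose element-count change disagrees with
#' the rule's declared fragment delta are discarded.
#'
#' @param rule a rule from a [load_rules()] collection.
#' @param m a `dn_mol` substrate.
#' @param direction `"forward"` or `"reverse"`.
#' @return a list of outcomes, each a list with `product` (a `dn_mol`),
#'   `site_atoms` (sorted substrate atom indices matched by the pattern),
#'   `product_site` (their images plus added atoms in the product),
#'   `rule_id` and `direction`. Empty list when the pattern does not match.
#' @examples
#' rules <- load_rules(system.file("extdata", "rules_bia.yaml", package = "derivnet"))
#' thc <- noscapine_pathway()$metabolites[["tetrahydrocolumbamine"]]
#' outs <- apply_rule(rules[["omt_aromatic"]], thc, "forward")
#' length(outs)  # one product per free phenolic hydroxyl
#' @export
apply_rule <- function(rule, m, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  stopifnot(inherits(m, "dn_mol"))
  dir <- rule[[direction]]
  matches <- .dn_match_pattern(dir$pattern, m)
  if (!length(matches)) return(list())
  # deterministic order
  ord <- order(vapply(matches, function(mp) paste(sprintf("%04d", mp), collapse = ""),
                      character(1)))
  matches <- matches[ord]
  out <- list(); seen <- character(0)
  for (mp in matches) {
    ed <- .dn_apply_edits(m, dir$pattern$ids, mp, dir$edits, name = "")
    if (is.null(ed)) next
    # element conservation against the declared fragment delta
    sub_c <- m$element_counts; prod_c <- ed$mol$element_counts
    all_e <- union(names(sub_c), names(prod_c))
    dv <- setNames(rep(0L, length(all_e)), all_e)
    dv[names(prod_c)] <- prod_c
    dv[names(sub_c)] <- dv[names(sub_c)] - sub_c
    dv <- dv[dv != 0L]
    decl <- dir$delta
    same <- length(dv) == length(decl) && setequal(names(dv), names(decl)) &&
      all(dv[names(decl)] == decl)
    if (!same) next
    if (sum(ed$mol$atoms$charge) - sum(m$atoms$charge) != dir$charge_delta) next
    key <- ed$mol$canonical_key
    if (key %in% seen) next
    if (key == m$canonical_key) next   # no-op rewrites never form an edge
    seen <- c(seen, key)
    prod_site <- sort(unlist(ed$trace, use.names = FALSE))
    out[[length(out) + 1L]] <- list(product = ed$mol,
                                    site_atoms = sort(unique(mp)),
                                    product_site = prod_site,
                                    rule_id = rule$rule_id,
                                    direction = direction)
  }
  out
}
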