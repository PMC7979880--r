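# Generalized bidirectional reaction rules: YAML schema, loading, validation.
#
# A rule file holds a list of rules. Each rule carries an EC-class tag, a
# cofactor context per direction (names only -- cofactors are never network
# nodes), and per direction a subgraph pattern plus a rewrite (edit script):
#
#   - rule_id: omt_aromatic
#     name: aromatic O-methylation
#     ec_prefix: 2.1.1.-
#     forward:
#       cofactors: {consumes: [SAM], produces: [SAH]}
#       delta: {C: 1, H: 2}
#       charge_delta: 0
#       pattern:
#         atoms:
#           - {id: p1, elem: C, arom: yes}
#           - {id: p2, elem: O, min_h: 1}
#         bonds:
#           - [p1, p2, 1]
#       edits:
#         - {op: add_atom, id: n1, elem: C}
#         - {op: add_bond, a: p2, b: n1, order: 1}
#     reverse: ...
#
# Pattern atom constraints: elem ("*" = any), arom (TRUE/FALSE, absent = any),
# min_h / max_h (implicit hydrogens), charge (absent = must be 0, "any"),
# min_deg / max_deg (heavy-atom degree). Bond order spec: 1/2/3 (Kekule
# order), "ar" (perceived aromatic), "-" (single and not aromatic), "any".
# Edit ops: add_atom, add_bond, set_bond, del_bond, set_charge, del_atom.

.dn_load_error <- function(rule_id, field, fmt, ...) {
  .dn_stop("dn_rule_load_error", "rule '%s', field '%s': %s", rule_id, field,
           sprintf(fmt, ...))
}

.dn_parse_pattern <- function(p, rule_id) {
  if (is.null(p$atoms) || !length(p$atoms))
    .dn_load_error(rule_id, "pattern", "pattern has no atoms")
  ids <- vapply(p$atoms, function(a) as.character(a$id %||% ""), character(1))
  if (any(!nzchar(ids)) || anyDuplicated(ids))
    .dn_load_error(rule_id, "pattern.atoms", "atom ids must be present and unique")
  atoms <- lapply(p$atoms, function(a) {
    list(id = as.character(a$id),
         elem = as.character(a$elem %||% "*"),
         arom = if (is.null(a$arom)) NA else isTRUE(a$arom),
         min_h = as.integer(a$min_h %||% 0L),
         max_h = if (is.null(a$max_h)) NA_integer_ else as.integer(a$max_h),
         charge = if (identical(a$charge, "any")) NA_integer_ else as.integer(a$charge %||% 0L),
         min_deg = if (is.null(a$min_deg)) NA_integer_ else as.integer(a$min_deg),
         max_deg = if (is.null(a$max_deg)) NA_integer_ else as.integer(a$max_deg))
  })
  bonds <- lapply(p$bonds %||% list(), function(b) {
    if (length(b) != 3L)
      .dn_load_error(rule_id, "pattern.bonds", "bond needs [id, id, order]")
    if (!all(c(b[[1L]], b[[2L]]) %in% ids))
      .dn_load_error(rule_id, "pattern.bonds", "bond references unknown atom id '%s'",
                     setdiff(c(b[[1L]], b[[2L]]), ids)[1L])
    list(a = match(b[[1L]], ids), b = match(b[[2L]], ids), order = as.character(b[[3L]]))
  })
  list(atoms = atoms, bonds = bonds, ids = ids)
}

.dn_parse_edits <- function(edits, pat_ids, rule_id) {
  known_ids <- pat_ids
  out <- lapply(edits %||% list(), function(e) {
    op <- as.character(e$op %||% "")
    if (!op %in% c("add_atom", "add_bond", "set_bond", "del_bond", "set_charge", "del_atom"))
      .dn_load_error(rule_id, "edits", "unknown op '%s'", op)
    if (op == "add_atom") {
      if (is.null(e$id) || e$id %in% known_ids)
        .dn_load_error(rule_id, "edits", "add_atom needs a fresh id")
      known_ids <<- c(known_ids, as.character(e$id))
      list(op = op, id = as.character(e$id), elem = as.character(e$elem %||% "C"),
           charge = as.integer(e$charge %||% 0L))
    } else if (op %in% c("add_bond", "set_bond", "del_bond")) {
      if (!all(c(e$a, e$b) %in% known_ids))
        .dn_load_error(rule_id, "edits", "%s references unknown id", op)
      list(op = op, a = as.character(e$a), b = as.character(e$b),
           order = as.integer(e$order %||% 1L))
    } else {
      if (!e$a %in% known_ids)
        .dn_load_error(rule_id, "edits", "%s references unknown id", op)
      list(op = op, a = as.character(e$a), charge = as.integer(e$charge %||% 0L))
    }
  })
  # every mapped (pattern) atom referenced by the rewrite must exist in the pattern:
  # enforced above through known_ids
  out
}

.dn_delta_vec <- function(d) {
  if (is.null(d)) return(integer(0))
  v <- setNames(as.integer(unlist(d)), names(d))
  v[v != 0L]
}

.dn_parse_direction <- function(d, rule_id, dirname) {
  if (is.null(d)) .dn_load_error(rule_id, dirname, "missing direction block")
  pat <- .dn_parse_pattern(d$pattern, rule_id)
  list(pattern = pat,
       edits = .dn_parse_edits(d$edits, pat$ids, rule_id),
       delta = .dn_delta_vec(d$delta),
       charge_delta = as.integer(d$charge_delta %||% 0L),
       cofactors = list(
         consumes = as.character(unlist(d$cofactors$consumes %||% character(0))),
         produces = as.character(unlist(d$cofactors$produces %||% character(0)))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a generalized reaction rule collection
#'
#' Reads a YAML rule file (see the packaged `rules_bia.yaml` for the schema),
#' validates each rule and checks at load time that the reverse element delta
#' is the exact negation of the forward delta (the two rewrites must be mutual
#' inverses on element counts).
#'
#' @param path path to a YAML rule file.
#' @return an object of class `dn_rules`: a named list of validated rules.
#' @export
load_rules <- function(path) {
  if (!file.exists(path))
    .dn_stop("dn_config_error", "rule file '%s' does not exist", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc) || !length(doc)) {
    warning("rule file '", path, "' contains no rules")
    return(structure(list(), class = "dn_rules", rule_set_id = basename(path)))
  }
  rules <- lapply(doc, function(r) {
    rid <- as.character(r$rule_id %||% "")
    if (!nzchar(rid)) .dn_load_error("(unnamed)", "rule_id", "missing rule_id")
    ec <- as.character(r$ec_prefix %||% "")
    if (!grepl("^\\d+\\.(\\d+|-)\\.(\\d+|-)\\.(\\d+|-)$", ec))
      .dn_load_error(rid, "ec_prefix", "malformed EC tag '%s'", ec)
    fwd <- .dn_parse_direction(r$forward, rid, "forward")
    rev <- .dn_parse_direction(r$reverse, rid, "reverse")
    all_e <- union(names(fwd$delta), names(rev$delta))
    f <- setNames(rep(0L, length(all_e)), all_e); f[names(fwd$delta)] <- fwd$delta
    b <- setNames(rep(0L, length(all_e)), all_e); b[names(rev$delta)] <- rev$delta
    if (length(all_e) && any(f + b != 0L))
      .dn_load_error(rid, "delta",
                     "reverse delta is not the negation of the forward delta")
    if (fwd$charge_delta + rev$charge_delta != 0L)
      .dn_load_error(rid, "charge_delta", "reverse charge delta must negate forward")
    list(rule_id = rid, name = as.character(r$name %||% rid), ec_prefix = ec,
         forward = fwd, reverse = rev)
  })
  names(rules) <- vapply(rules, `[[`, character(1), "rule_id")
  if (anyDuplicated(names(rules)))
    .dn_load_error(names(rules)[duplicated(names(rules))][1L], "rule_id", "duplicate rule_id")
  structure(rules, class = "dn_rules", rule_set_id = basename(path))
}

#' @export
print.dn_rules <- function(x, ...) {
  cat(sprintf("<ReactionRules> %d rules [%s]\n", length(x),
              attr(x, "rule_set_id") %||% "?"))
  for (r in x) cat(sprintf("  %-24s %-10s %s\n", r$rule_id, r$ec_prefix, r$name))
  invisible(x)
}

#' Cofactor context of a rule direction
#'
#' @param rule a rule from a [load_rules()] collection.
#' @param direction `"forward"` or `"reverse"`.
#' @return list with `consumes` and `produces` cofactor name vectors.
#' @export
cofactor_context <- function(rule, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  rule[[direction]]$cofactors
}
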