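# Structure parsing, canonicalization, elemental accounting and the
# benzylisoquinoline composition filter.
#
# Internal representation: a molecule is a hydrogen-suppressed colored graph.
#   atoms: data.frame(elem, charge, arom, nh)   -- nh = implicit hydrogens
#   bonds: data.frame(a1, a2, order, arom)      -- order = Kekule order (1/2/3),
#                                                  NA when only an aromatic flag
#                                                  was given in the input
# Implicit hydrogens are completed from a standard valence model; aromaticity
# is perceived once, repo-wide, on six-membered rings (see .dn_perceive_arom).
# All stereo descriptors are dropped on parsing: the generator treats
# stereoisomers as one constitution.

# allowed valences per element (first value >= bond sum is used for H fill)
.DN_VALENCES <- list(
  C = 4L, N = 3L, O = 2L, S = c(2L, 4L, 6L), P = c(3L, 5L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L, B = 3L, Se = c(2L, 4L, 6L), H = 1L
)

.dn_allowed_valence <- function(elem, charge) {
  v <- .DN_VALENCES[[elem]]
  if (is.null(v)) return(NULL)
  # charge shifts the preferred valence for the common organic cases:
  # N+ -> 4, N- -> 2, O+ -> 3, O- -> 1, C- -> 3
  if (elem %in% c("N", "O", "C", "S")) v <- v + charge
  v[v >= 0L]
}

.dn_stop <- function(class, fmt, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

# -- hydrogen completion -------------------------------------------------------

.dn_bond_sums <- function(n_atoms, bonds) {
  s <- numeric(n_atoms)
  if (nrow(bonds)) {
    ord <- ifelse(is.na(bonds$order), 1.5, bonds$order)
    for (k in seq_len(nrow(bonds))) {
      s[bonds$a1[k]] <- s[bonds$a1[k]] + ord[k]
      s[bonds$a2[k]] <- s[bonds$a2[k]] + ord[k]
    }
  }
  s
}

.dn_fill_hydrogens <- function(atoms, bonds) {
  sums <- floor(.dn_bond_sums(nrow(atoms), bonds))
  nh <- integer(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    allowed <- .dn_allowed_valence(atoms$elem[i], atoms$charge[i])
    if (is.null(allowed)) { nh[i] <- 0L; next }   # uncommon element: no H fill
    v <- allowed[allowed >= sums[i]]
    if (!length(v))
      .dn_stop("dn_chemistry_error",
               "atom %d (%s, charge %+d) has %d bonds, exceeding its maximal valence %d",
               i, atoms$elem[i], atoms$charge[i], sums[i], max(allowed))
    nh[i] <- as.integer(min(v) - sums[i])
  }
  atoms$nh <- nh
  atoms
}

# -- aromaticity perception ----------------------------------------------------

# Six-membered rings only (the repo-wide model): a ring is flagged aromatic when
# every ring bond has order 1/2 (or carries an input aromatic flag), every ring
# atom is C or N, and every ring atom bears at least one double or aromatic
# bond. This covers benzenoid rings and pyridinium-type cations; five-membered
# heteroaromatics and quinoid false positives are documented limitations.
.dn_six_rings <- function(n_atoms, bonds) {
  if (nrow(bonds) < 6L) return(list())
  adj <- vector("list", n_atoms)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$a1[k]]] <- c(adj[[bonds$a1[k]]], bonds$a2[k])
    adj[[bonds$a2[k]]] <- c(adj[[bonds$a2[k]]], bonds$a1[k])
  }
  rings <- list(); seen <- character()
  walk <- function(path) {
    last <- path[length(path)]
    for (nb in adj[[last]]) {
      if (length(path) == 6L) {
        if (nb == path[1L]) {
          key <- paste(sort(path), collapse = ",")
          if (!key %in% seen) { seen <<- c(seen, key); rings[[length(rings) + 1L]] <<- path }
        }
      } else if (nb > path[1L] && !nb %in% path) {
        walk(c(path, nb))
      }
    }
  }
  for (v in seq_len(n_atoms)) if (length(adj[[v]]) >= 2L) walk(v)
  rings
}

.dn_perceive_arom <- function(atoms, bonds) {
  atoms$arom <- FALSE
  if (nrow(bonds)) bonds$arom <- is.na(bonds$order) else bonds$arom <- logical(0)
  has_pi <- logical(nrow(atoms))
  if (nrow(bonds)) {
    pi_b <- which(bonds$order %in% 2L | is.na(bonds$order))
    has_pi[unique(c(bonds$a1[pi_b], bonds$a2[pi_b]))] <- TRUE
  }
  bond_idx <- function(i, j)
    which((bonds$a1 == i & bonds$a2 == j) | (bonds$a1 == j & bonds$a2 == i))
  for (ring in .dn_six_rings(nrow(atoms), bonds)) {
    if (!all(atoms$elem[ring] %in% c("C", "N"))) next
    if (!all(has_pi[ring])) next
    bidx <- integer(0); ok <- TRUE
    for (k in seq_len(6L)) {
      b <- bond_idx(ring[k], ring[k %% 6L + 1L])
      if (!length(b) || (!is.na(bonds$order[b[1L]]) && bonds$order[b[1L]] > 2L)) { ok <- FALSE; break }
      bidx <- c(bidx, b[1L])
    }
    if (!ok) next
    atoms$arom[ring] <- TRUE
    bonds$arom[bidx] <- TRUE
  }
  list(atoms = atoms, bonds = bonds)
}

# -- canonical key -------------------------------------------------------------

.dn_formula <- function(counts) {
  counts <- counts[counts > 0L]
  elems <- names(counts)
  ord <- c(intersect(c("C", "H"), elems), sort(setdiff(elems, c("C", "H"))))
  paste0(vapply(ord, function(e)
    paste0(e, if (counts[[e]] > 1L) counts[[e]] else ""), character(1)), collapse = "")
}

# Deterministic graph certificate: atoms and bonds become vertices of an
# auxiliary colored graph (bond vertices carry the bond order, or "~" for
# aromatic bonds, so Kekule alternatives of a perceived aromatic ring
# collapse to one key); igraph's BLISS canonical_permutation then yields a
# canonical serialization. Stable across runs and input atom orderings.
.dn_canonical_key <- function(atoms, bonds, counts) {
  na <- nrow(atoms); nb <- nrow(bonds)
  atype <- paste0(atoms$elem,
                  ifelse(atoms$charge != 0L, sprintf("%+d", atoms$charge), ""))
  btype <- ifelse(bonds$arom, "~", as.character(bonds$order))
  types <- c(atype, if (nb) paste0("|", btype) else character(0))
  g <- igraph::make_empty_graph(n = na + nb, directed = FALSE)
  if (nb) {
    ee <- rbind(cbind(bonds$a1, na + seq_len(nb)), cbind(bonds$a2, na + seq_len(nb)))
    g <- igraph::add_edges(g, t(ee))
  }
  colors <- match(types, sort(unique(types))) - 1L
  perm <- igraph::canonical_permutation(g, colors = colors)$labeling
  cg <- igraph::permute(g, perm)
  el <- igraph::as_edgelist(cg, names = FALSE)
  el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  paste0(.dn_formula(counts), "|",
         paste(types[order(perm)], collapse = ""), "|",
         paste(el[, 1L], el[, 2L], sep = "-", collapse = ";"))
}

# -- molecule constructor ------------------------------------------------------

.dn_element_counts <- function(atoms) {
  counts <- c(table(atoms$elem))
  counts <- setNames(as.integer(counts), names(counts))
  h <- sum(atoms$nh) + if ("H" %in% names(counts)) counts[["H"]] else 0L
  counts <- counts[names(counts) != "H"]
  counts[["H"]] <- as.integer(h)
  for (e in c("C", "H", "N")) if (is.na(counts[e])) counts[e] <- 0L
  counts[order(names(counts))]
}

# Build a Molecule from an atom/bond table; folds explicit hydrogens into
# implicit counts, completes valences, perceives aromaticity and computes the
# canonical key. Every rule application funnels back through here.
dn_mol <- function(atoms, bonds, name = "") {
  atoms$charge <- as.integer(atoms$charge)
  bonds$order <- as.integer(bonds$order)
  # fold explicit hydrogens (single-bonded H atoms) into neighbours
  hidx <- which(atoms$elem == "H")
  extra_h <- 0L
  if (length(hidx)) {
    keep <- setdiff(seq_len(nrow(atoms)), hidx)
    hb <- bonds$a1 %in% hidx | bonds$a2 %in% hidx
    extra_h <- sum(hb)
    bonds <- bonds[!hb, , drop = FALSE]
    remap <- match(seq_len(nrow(atoms)), keep)
    bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
    atoms <- atoms[keep, , drop = FALSE]
    rownames(atoms) <- NULL
  }
  if (!nrow(atoms)) .dn_stop("dn_parse_error", "structure has no atoms")
  if (any(bonds$a1 == bonds$a2))
    .dn_stop("dn_parse_error", "self-bond on atom %d", bonds$a1[bonds$a1 == bonds$a2][1L])
  # connectivity: multi-fragment input is rejected, not split
  if (nrow(atoms) > 1L) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = c(bonds$a1, seq_len(nrow(atoms))),
                 to = c(bonds$a2, seq_len(nrow(atoms)))),
      directed = FALSE)
    if (igraph::count_components(g) > 1L)
      .dn_stop("dn_parse_error",
               "structure has %d disconnected fragments; single-fragment neutral input required",
               igraph::count_components(g))
  }
  atoms <- .dn_fill_hydrogens(atoms, bonds)
  ar <- .dn_perceive_arom(atoms, bonds)
  atoms <- ar$atoms; bonds <- ar$bonds
  counts <- .dn_element_counts(atoms)
  counts[["H"]] <- counts[["H"]] + extra_h
  m <- structure(list(name = name, atoms = atoms, bonds = bonds,
                      element_counts = counts,
                      canonical_key = .dn_canonical_key(atoms, bonds, counts)),
                 class = "dn_mol")
  m
}

#' @export
print.dn_mol <- function(x, ...) {
  cat(sprintf("<Molecule> %s\n  formula: %s\n  atoms: %d heavy, bonds: %d\n  key: %s...\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              .dn_formula(x$element_counts),
              nrow(x$atoms), nrow(x$bonds),
              substr(x$canonical_key, 1L, 40L)))
  invisible(x)
}

# -- molfile reading -----------------------------------------------------------

.dn_read_molfile <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  if (length(lines) < 4L)
    .dn_stop("dn_parse_error", "molfile too short: %d lines", length(lines))
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  body <- sub("\\s+$", "", lines)
  if (!any(grepl("^M  END", body))) body <- c(body, "M  END")
  writeLines(c(body[seq_len(max(which(grepl("^M  END", body))))], "$$$$"), tf)
  sdf <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(tf)),
                  error = function(e) .dn_stop("dn_parse_error", "molfile rejected: %s",
                                               conditionMessage(e)))
  if (length(sdf) < 1L) .dn_stop("dn_parse_error", "no structure found in molfile")
  ab <- ChemmineR::atomblock(sdf[[1L]])
  bb <- ChemmineR::bondblock(sdf[[1L]])
  if (is.null(dim(ab)) || nrow(ab) == 0L)
    .dn_stop("dn_parse_error", "molfile atom block is empty")
  elem <- sub("_.*$", "", rownames(ab))
  atoms <- data.frame(elem = elem, charge = 0L, arom = FALSE, nh = 0L,
                      stringsAsFactors = FALSE)
  # charges: M CHG lines override; fall back to the old-style atom-line code
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines)) {
    for (cl in chg_lines) {
      f <- as.integer(strsplit(trimws(substr(cl, 7L, nchar(cl))), "\\s+")[[1L]])
      n <- f[1L]
      for (k in seq_len(n)) atoms$charge[f[2L * k]] <- f[2L * k + 1L]
    }
  } else if (ncol(ab) >= 5L) {
    code <- ab[, 5L]
    old <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
    hit <- code %in% as.integer(names(old))
    atoms$charge[hit] <- unname(old[as.character(code[hit])])
  }
  if (is.null(dim(bb)) || nrow(bb) == 0L) {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
                        arom = logical(0))
  } else {
    ord <- as.integer(bb[, 3L])
    bad <- which(!ord %in% c(1L, 2L, 3L, 4L))
    if (length(bad))
      .dn_stop("dn_parse_error", "unsupported bond type %d on bond line %d", ord[bad[1L]], bad[1L])
    bonds <- data.frame(a1 = as.integer(bb[, 1L]), a2 = as.integer(bb[, 2L]),
                        order = ifelse(ord == 4L, NA_integer_, ord),
                        arom = ord == 4L)
    if (any(bonds$a1 > nrow(atoms) | bonds$a2 > nrow(atoms) | bonds$a1 < 1L | bonds$a2 < 1L))
      .dn_stop("dn_parse_error", "bond references atom outside the atom block")
  }
  name <- trimws(lines[1L])
  dn_mol(atoms, bonds, name = name)
}

.dn_read_smiles <- function(text) {
  smi <- trimws(text)
  if (grepl("\\s", smi)) {
    parts <- strsplit(smi, "\\s+")[[1L]]
    smi <- parts[1L]
  }
  # strip stereo descriptors up front: the network generator ignores them
  smi_flat <- gsub("@|/|\\\\", "", smi)
  sdf <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smi_flat, " mol")),
    error = function(e) .dn_stop("dn_parse_error", "SMILES rejected: %s", conditionMessage(e)))
  if (!nzchar(sdf) || !grepl("V2000", sdf))
    .dn_stop("dn_parse_error", "SMILES '%s' could not be interpreted", smi)
  .dn_read_molfile(sdf)
}

#' Parse a chemical structure into a Molecule
#'
#' Reads an MDL molfile (V2000) or a SMILES string, suppresses explicit
#' hydrogens and all stereo descriptors, completes implicit hydrogens from a
#' standard valence model, perceives six-membered-ring aromaticity and computes
#' a deterministic stereo-free canonical key (the deduplication key used across
#' the whole network expansion).
#'
#' @param text structure document: molfile text or a SMILES string.
#' @param format `"molfile"` or `"smiles"`.
#' @param name optional compound label; defaults to the molfile title line.
#' @return an object of class `dn_mol` with fields `name`, `atoms`, `bonds`,
#'   `element_counts` (named integer vector; C, H and N always present) and
#'   `canonical_key`.
#' @examples
#' m <- parse_structure("Oc1ccc(CC2NCCc3cc(O)c(O)cc23)cc1", "smiles",
#'                      name = "norcoclaurine")
#' m$element_counts[c("C", "H", "N", "O")]
#' @export
parse_structure <- function(text, format = c("molfile", "smiles"), name = NULL) {
  format <- match.arg(format)
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    .dn_stop("dn_parse_error", "empty structure document")
  m <- if (format == "molfile") .dn_read_molfile(text) else .dn_read_smiles(text)
  if (!is.null(name)) m$name <- name
  m
}

# -- writers -------------------------------------------------------------------

#' Emit a Molecule as MDL molfile (V2000) text
#'
#' Coordinates are written as zeros (the package stores connectivity only);
#' perceived aromatic bonds of known Kekule order are written with that order,
#' aromatic-only bonds as type 4. Charges are written as `M  CHG` lines.
#'
#' @param m a `dn_mol`.
#' @return a single molfile string, terminated by `M  END`.
#' @export
molfile_text <- function(m) {
  stopifnot(inherits(m, "dn_mol"))
  a <- m$atoms; b <- m$bonds
  lines <- c(m$name, "  derivnet", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b)))
  lines <- c(lines, vapply(seq_len(nrow(a)), function(i)
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            0, 0, 0, a$elem[i]), character(1)))
  if (nrow(b))
    lines <- c(lines, vapply(seq_len(nrow(b)), function(k)
      sprintf("%3d%3d%3d  0  0  0  0", b$a1[k], b$a2[k],
              if (is.na(b$order[k])) 4L else b$order[k]), character(1)))
  chg <- which(a$charge != 0L)
  for (i in chg) lines <- c(lines, sprintf("M  CHG%3d%4d%4d", 1L, i, a$charge[i]))
  paste0(paste(c(lines, "M  END"), collapse = "\n"), "\n")
}

#' Emit a Molecule as a canonical SMILES string
#'
#' Conversion goes through OpenBabel's canonical SMILES writer from the
#' package's molfile emission; used for display and file export (the package's
#' own `canonical_key` remains the deduplication key).
#'
#' @param m a `dn_mol`.
#' @return a SMILES string.
#' @export
smiles_text <- function(m) {
  out <- ChemmineOB::convertFormat("SDF", "CAN", paste0(molfile_text(m), "$$$$\n"))
  strsplit(trimws(out), "\\s+")[[1L]][1L]
}

# -- composition filter --------------------------------------------------------

#' Minimal elemental composition filter for the benzylisoquinoline scaffold
#'
#' The expansion analysis keeps only compounds containing at least the
#' elemental composition of the 1-benzylisoquinoline scaffold: 16 carbon,
#' 13 hydrogen and 1 nitrogen atoms by default.
#'
#' @param min_c,min_h,min_n non-negative thresholds.
#' @return a `dn_filter` specification.
#' @export
bia_filter <- function(min_c = 16L, min_h = 13L, min_n = 1L) {
  stopifnot(min_c >= 0L, min_h >= 0L, min_n >= 0L)
  structure(list(min_c = as.integer(min_c), min_h = as.integer(min_h),
                 min_n = as.integer(min_n)), class = "dn_filter")
}

#' Test a Molecule against a composition filter
#'
#' @param m a `dn_mol`.
#' @param spec a [bia_filter()] specification.
#' @return `TRUE` iff the molecule has at least `min_c` carbons, `min_h`
#'   hydrogens and `min_n` nitrogens.
#' @export
passes_filter <- function(m, spec = bia_filter()) {
  stopifnot(inherits(m, "dn_mol"), inherits(spec, "dn_filter"))
  ec <- m$element_counts
  ec[["C"]] >= spec$min_c && ec[["H"]] >= spec$min_h && ec[["N"]] >= spec$min_n
}
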