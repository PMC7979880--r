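# Reactive sites, reaction fingerprints, similarity scoring, enzyme ranking,
# pathway feasibility.

test_that("the reactive site of an O-methylation covers the phenolic oxygen and its ring carbon", {
  st <- dn_state()
  thc <- st$pathway$metabolites[["tetrahydrocolumbamine"]]
  out <- apply_rule(st$rules[["omt_aromatic"]], thc, "forward")[[1]]
  rxn <- as_reaction(thc, out$product, st$rules[["omt_aromatic"]])
  site <- reactive_site(rxn)
  expect_setequal(site$substrate, out$site_atoms)
  elems <- thc$atoms$elem[site$substrate]
  expect_true("O" %in% elems)
  expect_true(any(thc$atoms$arom[site$substrate] & elems == "C"))
  expect_true(all(site$substrate <= nrow(thc$atoms)))
  # the product side additionally holds the introduced methyl carbon
  expect_identical(length(site$product), length(site$substrate) + 1L)
})

test_that("re-matching a stored edge reproduces its recorded site atoms", {
  st <- dn_state()
  net <- st$trimmed
  idx <- which(net$edges$rule_id == "omt_aromatic")[1:5]
  for (i in idx) {
    e <- net$edges[i, ]
    rxn_stored <- edge_reaction(net, i)
    rxn_rematch <- as_reaction(net$compounds[[e$substrate_key]]$mol,
                               net$compounds[[e$product_key]]$mol,
                               st$rules[[e$rule_id]])
    expect_setequal(rxn_stored$sub_site, rxn_rematch$sub_site)
  }
  # a rule that does not produce the claimed product is a consistency error
  expect_error(as_reaction(st$pathway$metabolites[["canadine"]],
                           st$pathway$metabolites[["noscapine"]],
                           st$rules[["omt_aromatic"]]),
               class = "dn_consistency_error")
})

test_that("fingerprints are deterministic and depth-1 is substrate-independent for phenol methylation", {
  st <- dn_state()
  cfg <- similarity_config()
  mk <- function(smi) {
    m <- parse_structure(smi, "smiles")
    o <- apply_rule(st$rules[["omt_aromatic"]], m, "forward")[[1]]
    as_reaction(m, o$product, st$rules[["omt_aromatic"]])
  }
  r1 <- mk("Oc1ccccc1")            # phenol
  r2 <- mk("Oc1ccccc1O")           # catechol: differs two bonds from the site
  f1 <- reaction_fingerprint(r1, cfg); f2 <- reaction_fingerprint(r2, cfg)
  expect_identical(f1$levels[[1]], f2$levels[[1]])
  expect_false(identical(f1$levels[[2]], f2$levels[[2]]))
  expect_gt(length(f1$levels[[1]]), 0L)
  # identical reactions give identical fingerprints
  expect_identical(reaction_fingerprint(mk("Oc1ccccc1"), cfg), f1)
})

test_that("reactions identical within the depth horizon share a fingerprint", {
  st <- dn_state()
  # methylation of the para-hydroxyl of two long-chain phenols that differ
  # only beyond 7 bonds from the site
  mk <- function(smi) {
    m <- parse_structure(smi, "smiles")
    outs <- apply_rule(st$rules[["omt_aromatic"]], m, "forward")
    as_reaction(m, outs[[1]]$product, st$rules[["omt_aromatic"]])
  }
  a <- mk("Oc1ccc(CCCCCCCCC)cc1")
  b <- mk("Oc1ccc(CCCCCCCCN)cc1")   # N vs C at distance 9 from the ring
  fa <- reaction_fingerprint(a, similarity_config(7))
  fb <- reaction_fingerprint(b, similarity_config(7))
  expect_identical(fa, fb)
  expect_equal(reaction_similarity(fa, fb), 1.0)
})

test_that("similarity is a bounded symmetric score with 1.0 on identity", {
  st <- dn_state()
  cfg <- similarity_config()
  refs <- attr(st$reference, "reactions")
  fps <- lapply(refs[1:10], reaction_fingerprint, config = cfg)
  for (i in seq_along(fps)) {
    expect_equal(reaction_similarity(fps[[i]], fps[[i]]), 1.0)
    for (j in seq_along(fps)) {
      s <- reaction_similarity(fps[[i]], fps[[j]])
      expect_gte(s, 0); expect_lte(s, 1)
      expect_equal(s, reaction_similarity(fps[[j]], fps[[i]]))
    }
  }
  # disjoint feature sets score exactly zero
  mkfp <- function(tag) structure(list(
    levels = lapply(1:7, function(d) sprintf("S:%d:%s{}", d, tag)),
    max_depth = 7L), class = "dn_fingerprint")
  expect_equal(reaction_similarity(mkfp("NH1"), mkfp("OH1")), 0)
  nmt <- refs[["R019"]]; omt <- refs[["R008"]]
  expect_error(reaction_similarity(reaction_fingerprint(nmt, cfg),
                                   reaction_fingerprint(omt, similarity_config(3))),
               class = "dn_config_error")
})

test_that("similarity equals a naive from-scratch recomputation on fixture pairs", {
  st <- dn_state()
  cfg <- similarity_config()
  refs <- attr(st$reference, "reactions")
  # oracle: recompute the per-depth feature sets with adjacency-matrix
  # reachability (matrix powers) instead of the package's BFS, then take the
  # plain mean of Jaccard overlaps
  oracle_feats <- function(mol, site, side, depth) {
    n <- nrow(mol$atoms)
    A <- matrix(0L, n, n)
    for (k in seq_len(nrow(mol$bonds))) {
      A[mol$bonds$a1[k], mol$bonds$a2[k]] <- 1L
      A[mol$bonds$a2[k], mol$bonds$a1[k]] <- 1L
    }
    lab <- function(i) paste0(mol$atoms$elem[i],
                              if (mol$atoms$charge[i] != 0)
                                sprintf("%+d", mol$atoms$charge[i]) else "",
                              if (mol$atoms$arom[i]) "a" else "",
                              "H", mol$atoms$nh[i])
    dist <- matrix(Inf, n, n); diag(dist) <- 0
    P <- diag(n)
    for (d in seq_len(depth)) {
      P <- P %*% A
      newly <- which(P > 0 & is.infinite(dist))
      dist[newly] <- d
    }
    unlist(lapply(sort(site), function(a) {
      vapply(seq_len(depth), function(dd) {
        nb <- which(is.finite(dist[a, ]) & dist[a, ] <= dd - 1 & dist[a, ] > 0)
        paste0(side, ":", dd, ":", lab(a), "{",
               paste(sort(paste0(dist[a, nb], "-", vapply(nb, lab, character(1)))),
                     collapse = ","), "}")
      }, character(1))
    }))
  }
  oracle_sim <- function(ra, rb, depth) {
    fa <- c(oracle_feats(ra$substrate, ra$sub_site, "S", depth),
            oracle_feats(ra$product, ra$prod_site, "P", depth))
    fb <- c(oracle_feats(rb$substrate, rb$sub_site, "S", depth),
            oracle_feats(rb$product, rb$prod_site, "P", depth))
    per_depth <- vapply(seq_len(depth), function(dd) {
      sa <- unique(grep(paste0("^[SP]:", dd, ":"), fa, value = TRUE))
      sb <- unique(grep(paste0("^[SP]:", dd, ":"), fb, value = TRUE))
      if (!length(sa) && !length(sb)) return(1)
      length(intersect(sa, sb)) / length(union(sa, sb))
    }, numeric(1))
    mean(per_depth)
  }
  set.seed(7)
  ids <- names(refs)
  for (k in 1:10) {
    pick <- sample(ids, 2L)
    got <- reaction_similarity(reaction_fingerprint(refs[[pick[1]]], cfg),
                               reaction_fingerprint(refs[[pick[2]]], cfg))
    expect_equal(got, oracle_sim(refs[[pick[1]]], refs[[pick[2]]], cfg$max_depth),
                 info = paste(pick, collapse = " vs "))
  }
})

test_that("enzyme ranking removes sequence-less entries and finds identity at rank 1", {
  st <- dn_state()
  ret <- st$pathway$metabolites[["reticuline"]]
  cat_b <- st$catalogs$biological
  lau <- parse_structure(cat_b$smiles[cat_b$name == "Laudanine"], "smiles")
  rxn <- as_reaction(ret, lau, st$rules[["omt_aromatic"]])
  cand <- rank_enzymes(rxn, st$reference)
  # the reference holds this exact reaction (reticuline 7-O-methylation)
  expect_identical(cand$reference_id[1], "R001")
  expect_equal(cand$score[1], 1.0)
  expect_identical(cand$rank, seq_len(nrow(cand)))
  expect_true(all(diff(cand$score) <= 0))
  # the orphan entry (no sequence annotation) never appears
  expect_false("R022" %in% cand$reference_id)
  expect_false(any(!st$reference$has_sequence[match(cand$reference_id,
                                                    st$reference$reaction_id)]))
  # one best row per EC class
  expect_identical(anyDuplicated(cand$ec), 0L)
})

test_that("ranking order is stable under reference permutation and the sequence filter preserves relative order", {
  st <- dn_state()
  thc <- st$pathway$metabolites[["tetrahydrocolumbamine"]]
  out <- apply_rule(st$rules[["omt_aromatic"]], thc, "forward")[[1]]
  rxn <- as_reaction(thc, out$product, st$rules[["omt_aromatic"]])
  ref <- st$reference
  perm <- ref[rev(seq_len(nrow(ref))), ]
  attr(perm, "reactions") <- attr(ref, "reactions")
  c1 <- rank_enzymes(rxn, ref)
  c2 <- rank_enzymes(rxn, perm)
  expect_identical(c1$reference_id, c2$reference_id)
  expect_identical(c1$score, c2$score)
  # scoring against all entries, then filtering, keeps survivor order
  all_seq <- ref; all_seq$has_sequence <- TRUE
  attr(all_seq, "reactions") <- attr(ref, "reactions")
  c3 <- rank_enzymes(rxn, all_seq)
  expect_identical(c3$reference_id[c3$reference_id %in% c1$reference_id],
                   c1$reference_id)
})

test_that("significance filtering is strictly above the threshold", {
  cand <- data.frame(rank = 1:3, score = c(0.31, 0.30, 0.05),
                     ec = c("2.1.1.1", "2.1.1.2", "2.1.1.3"))
  kept <- significant_candidates(cand, similarity_config(threshold = 0.3))
  expect_identical(kept$ec, "2.1.1.1")
  expect_identical(nrow(significant_candidates(cand[0, ], similarity_config())), 0L)
})

test_that("pathway feasibility is the mean of per-step top scores within component bounds", {
  st <- dn_state()
  g <- build_pair_graph(st$trimmed, search_config())
  cat_b <- st$catalogs$biological
  seeds <- vapply(st$pathway$metabolites, function(m) m$canonical_key, character(1))
  for (target_name in c("Tetrahydropalmatine", "Nandinine", "Palmatine")) {
    tkey <- cat_b$key[cat_b$name == target_name]
    paths <- enumerate_pathways(g, unname(seeds), tkey, search_config())
    expect_gt(length(paths), 0L, label = target_name)
    for (p in paths[seq_len(min(3, length(paths)))]) {
      ps <- pathway_feasibility(p, st$trimmed, st$reference)
      expect_length(ps$step_scores, p$length)
      expect_equal(ps$mean_top_score, mean(ps$step_scores))
      expect_gte(ps$mean_top_score, min(ps$step_scores))
      expect_lte(ps$mean_top_score, max(ps$step_scores))
    }
  }
  # a known seed-pathway step scores 1.0 by convention
  pw_edge <- which(st$trimmed$edges$status == "known")[1]
  fake_path <- structure(list(source = st$trimmed$edges$substrate_key[pw_edge],
                              target = st$trimmed$edges$product_key[pw_edge],
                              steps = data.frame(
                                from = st$trimmed$edges$substrate_key[pw_edge],
                                to = st$trimmed$edges$product_key[pw_edge],
                                rule_id = st$trimmed$edges$rule_id[pw_edge],
                                travelled = "forward",
                                edge_index = pw_edge,
                                arc_id = "x"),
                              length = 1L), class = "dn_path")
  ps <- pathway_feasibility(fake_path, st$trimmed, st$reference)
  expect_equal(ps$mean_top_score, 1.0)
})
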