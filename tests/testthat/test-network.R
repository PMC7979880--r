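# Network expansion, known-compound restriction, trimming, classification,
# exports.

test_that("expansion restricted to catalogued compounds recovers the pathway and derivatives", {
  st <- dn_state()
  net <- st$network
  # all seeds at generation 0
  for (m in st$pathway$metabolites)
    expect_identical(net$compounds[[m$canonical_key]]$generation, 0L)
  # every seed pathway reaction was regenerated by a rule
  for (i in seq_len(nrow(st$pathway$reactions))) {
    rx <- st$pathway$reactions[i, ]
    sk <- st$pathway$metabolites[[rx$substrate]]$canonical_key
    pk <- st$pathway$metabolites[[rx$product]]$canonical_key
    expect_true(any(net$edges$substrate_key == sk & net$edges$product_key == pk),
                info = paste(rx$substrate, "->", rx$product))
  }
  # the experimentally relevant one-step derivatives sit at generation 1
  for (nm in c("Tetrahydropalmatine", "Armepavine", "Laudanine", "Nandinine",
               "Berberine", "Columbamine"))
    expect_identical(dn_gen_of_name(net, nm), 1L, info = nm)
  # palmatine needs two steps
  expect_identical(dn_gen_of_name(net, "Palmatine"), 2L)
})

test_that("products outside the catalogs are discarded under known_only", {
  st <- dn_state()
  # aromatic hydroxylation of norcoclaurine yields several phenols; only
  # norlaudanosoline is catalogued, the others must be absent
  nor <- st$pathway$metabolites[["norcoclaurine"]]
  outs <- apply_rule(st$rules[["hydroxylation_aromatic"]], nor, "forward")
  keys <- vapply(outs, function(o) o$product$canonical_key, character(1))
  lookup <- catalog_lookup(st$catalogs)
  uncat <- setdiff(keys, names(lookup$class))
  expect_gt(length(uncat), 0L)
  for (k in uncat) expect_null(st$network$compounds[[k]])
  expect_false(is.null(st$network$compounds[[intersect(keys, names(lookup$class))[1]]]))
})

test_that("zero generations give the seeds only, and the guard rejects excess", {
  st <- dn_state()
  net0 <- expand_network(st$pathway, st$rules, st$catalogs, expansion_config(0))
  expect_length(net0$compounds, 17L)
  expect_identical(nrow(net0$edges), 0L)
  expect_error(expansion_config(11), class = "dn_config_error")
  expect_error(expansion_config(-1), class = "dn_config_error")
})

test_that("expansion is deterministic and monotone in generations", {
  st <- dn_state()
  n1 <- expand_network(st$pathway, st$rules, st$catalogs, expansion_config(1))
  n1b <- expand_network(st$pathway, st$rules, st$catalogs, expansion_config(1))
  expect_identical(sort(names(n1$compounds)), sort(names(n1b$compounds)))
  eid <- function(n) sort(paste(n$edges$substrate_key, n$edges$product_key,
                                n$edges$rule_id))
  expect_identical(eid(n1), eid(n1b))
  n2 <- expand_network(st$pathway, st$rules, st$catalogs, expansion_config(2))
  expect_true(all(names(n1$compounds) %in% names(n2$compounds)))
  expect_true(all(names(n2$compounds) %in% names(st$network$compounds)))
})

test_that("small-seed expansion matches a brute-force enumerator", {
  st <- dn_state()
  rules <- st$rules[c("omt_aromatic", "hydroxylation_aromatic")]
  class(rules) <- "dn_rules"; attr(rules, "rule_set_id") <- "mini"
  seeds <- list(parse_structure("Oc1ccccc1O", "smiles", name = "catechol"),
                parse_structure("COc1ccccc1O", "smiles", name = "guaiacol"))
  cfg <- expansion_config(2, known_only = FALSE)
  net <- expand_network(seeds, rules, NULL, cfg)
  # oracle: plain nested loops trying every rule on every molecule each round;
  # products of the last round are recorded as reaction partners only when
  # they already exist (no new nodes at the horizon)
  pool <- stats::setNames(seeds, vapply(seeds, function(m) m$canonical_key,
                                        character(1)))
  pairs <- character(0)
  n_rounds <- 2L
  for (round in seq_len(n_rounds)) {
    current <- pool
    for (m in current) for (r in rules) for (d in c("forward", "reverse")) {
      for (o in apply_rule(r, m, d)) {
        k <- o$product$canonical_key
        if (round < n_rounds) pool[[k]] <- o$product
        pairs <- c(pairs, if (d == "forward")
          paste(m$canonical_key, k, r$rule_id)
          else paste(k, m$canonical_key, r$rule_id))
      }
    }
  }
  expect_setequal(names(net$compounds), names(pool))
  got_pairs <- paste(net$edges$substrate_key, net$edges$product_key,
                     net$edges$rule_id)
  keep <- vapply(strsplit(unique(pairs), " ", fixed = TRUE), function(p)
    all(p[1:2] %in% names(pool)), logical(1))
  expect_setequal(got_pairs, unique(pairs)[keep])
})

test_that("trimming keeps exactly the scaffold-compatible compounds and is idempotent", {
  st <- dn_state()
  net <- st$network
  # inject a small molecule plus an incident edge, then trim
  meoh <- parse_structure("CO", "smiles", name = "methanol")
  net2 <- net
  net2$compounds[[meoh$canonical_key]] <-
    list(mol = meoh, name = "methanol", generation = 1L, catalog_class = "chemical")
  fake <- net2$edges[1, ]
  fake$product_key <- meoh$canonical_key
  net2$edges <- rbind(net2$edges, fake)
  tr <- trim_network(net2, bia_filter())
  expect_null(tr$compounds[[meoh$canonical_key]])
  expect_false(any(tr$edges$product_key == meoh$canonical_key))
  # all 17 pathway metabolites are retained
  for (m in st$pathway$metabolites)
    expect_false(is.null(tr$compounds[[m$canonical_key]]), info = m$name)
  # idempotence
  tr2 <- trim_network(tr, bia_filter())
  expect_identical(names(tr2$compounds), names(tr$compounds))
  expect_identical(tr2$edges, tr$edges)
})

test_that("reactions are classified known via the reference db or the seed pathway", {
  st <- dn_state()
  pw <- st$pathway
  sk <- pw$metabolites[["norcoclaurine"]]$canonical_key
  pk <- pw$metabolites[["coclaurine"]]$canonical_key
  e <- list(substrate_key = sk, product_key = pk, rule_id = "omt_aromatic")
  expect_identical(classify_reaction(e, NULL, pw), "known")
  expect_identical(classify_reaction(e, st$reference, NULL), "known")  # R003
  novel <- list(substrate_key = "x", product_key = "y", rule_id = "omt_aromatic")
  expect_identical(classify_reaction(novel, st$reference, pw), "novel")
  # annotated fixture network: the canadine -> berberine oxidation is known
  cat <- st$catalogs$biological
  bk <- cat$key[cat$name == "Berberine"]
  ck <- pw$metabolites[["canadine"]]$canonical_key
  row <- st$network$edges[st$network$edges$substrate_key == ck &
                            st$network$edges$product_key == bk, ]
  expect_identical(unique(row$status), "known")
})

test_that("network exports are well-formed GraphML and JSON", {
  st <- dn_state()
  g <- tempfile(fileext = ".graphml")
  write_network_graphml(st$trimmed, g)
  doc <- xml2::read_xml(g)
  expect_identical(xml2::xml_name(doc), "graphml")
  nodes <- xml2::xml_find_all(doc, ".//*[local-name()='node']")
  expect_length(nodes, length(st$trimmed$compounds))
  j <- tempfile(fileext = ".json")
  write_network_json(st$trimmed, j, smiles = FALSE)
  parsed <- jsonlite::read_json(j)
  expect_identical(length(parsed$compounds), length(st$trimmed$compounds))
  expect_identical(length(parsed$reactions), nrow(st$trimmed$edges))
  expect_identical(parsed$config$generations, 4L)
  unlink(c(g, j))
})
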