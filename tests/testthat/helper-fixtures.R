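# Shared fixture state, computed once per test run: the packaged pathway,
# rules, catalogs, reference database, and the 4-generation expanded network
# (annotated and trimmed). Everything is built in code from packaged
# plain-text fixtures.

.dn_test_env <- new.env(parent = emptyenv())

dn_state <- function() {
  if (is.null(.dn_test_env$state)) {
    pathway <- noscapine_pathway()
    rules <- bia_rules()
    catalogs <- mini_catalogs()
    reference <- mini_reference_db()
    net <- expand_network(pathway, rules, catalogs, expansion_config(4))
    net <- annotate_network(net, reference, pathway)
    trimmed <- trim_network(net, bia_filter())
    .dn_test_env$state <- list(pathway = pathway, rules = rules,
                               catalogs = catalogs, reference = reference,
                               annotations = annotation_table(),
                               network = net, trimmed = trimmed)
  }
  .dn_test_env$state
}

dn_name_of <- function(net, key) net$compounds[[key]]$name

dn_gen_of_name <- function(net, nm) {
  hit <- Filter(function(cp) identical(cp$name, nm), net$compounds)
  if (!length(hit)) NA_integer_ else hit[[1L]]$generation
}
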