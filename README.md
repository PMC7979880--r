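# derivnet

Systematic exploration of the biochemical vicinity of a heterologous
biosynthetic pathway: which natural-product derivatives could be produced by
derivatizing pathway intermediates, and which enzymes might catalyze those
derivatizations?

`derivnet` is aimed at metabolic engineers and synthetic biologists who have
reconstituted a plant natural-product pathway in a microbial host and want
computational guidance on one-enzyme pathway extensions. The package
implements the full workflow on a self-contained benzylisoquinoline alkaloid
(BIA) fixture — the noscapine pathway from (S)-norcoclaurine, 17 metabolites
connected by 17 reactions catalyzed by 11 generalized reaction-rule classes —
so everything runs offline, with no database downloads.

## The method

1. **Rule-based network expansion.** Generalized enzymatic reaction rules —
   bidirectional subgraph rewrites tagged with a third-level EC class and a
   cofactor context (e.g. SAM→SAH for methylations) — are applied iteratively
   to the pathway metabolites. At generation *g + 1* every rule is applied in
   both directions to every compound of generation ≤ *g*; products are
   canonicalized on a stereo-free graph certificate and kept only when they
   occur in a *biological*, *bioactive* or *chemical* compound catalog
   ("only known molecular structures enter the network"). Reactions are
   *known* if present in a reference reaction database or the seed pathway,
   otherwise *novel*.
2. **Scaffold trimming.** The network is restricted to compounds with at
   least the elemental composition of the 1-benzylisoquinoline scaffold:
   C ≥ 16, H ≥ 13, N ≥ 1.
3. **Popularity ranking.** Candidates are ranked by *popularity* = citations
   + patents; compounds without a single annotation are dropped, and the
   search can be restricted to candidates one reaction step from a pathway
   intermediate.
4. **Pathway enumeration.** All simple directed pathways from any pathway
   intermediate to a target within 4 steps are extracted from the
   reactant–product graph. Directions producing molecular oxygen, binding
   CO₂ to the substrate (reverse decarboxylation) or demethylating via
   SAH→SAM are excluded.
5. **Enzyme candidate ranking.** Each novel reaction is fingerprinted on and
   around its reactive site (per-depth atom-environment shells, radius 1–7
   bonds, on substrate and product sides) and scored in [0, 1] against a
   reference database of gene-annotated reactions; entries without a protein
   sequence are removed, scores strictly above 0.3 count as significant, and
   a pathway's enzymatic feasibility is the mean of its per-step top scores.

## Worked example

```r
library(derivnet)

pathway <- noscapine_pathway()
pathway
#> <PathwayDefinition> noscapine: 17 metabolites, 17 reactions, 11 rule classes

net <- expand_network(pathway, bia_rules(), mini_catalogs(),
                      expansion_config(generations = 4))
net <- annotate_network(net, mini_reference_db(), pathway)
net
#> <Network> 31 compounds, 41 reactions (4 generations run)
#> generation
#>  0  1  2
#> 17 12  2

trimmed <- trim_network(net, bia_filter())   # C>=16, H>=13, N>=1
report  <- rank_candidates(trimmed, annotation_table(), exclude = pathway)
one_step_candidates(report, trimmed, pathway)[, 1:5]
#>   rank                name popularity citations patents
#> 1    1           Berberine      12181      5430    6751
#> 2    2 Tetrahydropalmatine        885       530     355
#> 3    3         Columbamine        366       131     235
#> 4    4    Norlaudanosoline        321       144     177
#> 5    5           Laudanine        135        23     112
#> ...
```

Nine annotated compounds sit one reaction from a pathway intermediate.
Berberine ranks first (its heterologous biosynthesis is already
established); tetrahydropalmatine — an analgesic and anxiolytic from
*Corydalis* — ranks second, produced by a single O-methylation of
(S)-tetrahydrocolumbamine. Ranking the reference enzymes for that reaction:

```r
rules <- bia_rules()
thc <- pathway$metabolites[["tetrahydrocolumbamine"]]
thp <- apply_rule(rules[["omt_aromatic"]], thc, "forward")[[1]]$product
rxn <- as_reaction(thc, thp, rules[["omt_aromatic"]])
head(rank_enzymes(rxn, mini_reference_db()), 2)[, 1:4]
#>   rank     score        ec native_substrate
#> 1    1 0.7913832 2.1.1.291   (S)-reticuline
#> 2    2 0.5056689 2.1.1.118      Columbamine
```

The top candidates are reticuline 7-O-methyltransferase (EC 2.1.1.291) and
columbamine O-methyltransferase (EC 2.1.1.118, *Coptis japonica*) — BIA
O-methyltransferases whose native substrates closely resemble
tetrahydrocolumbamine. The KEGG-style orphan entry for the reaction itself
(no sequence annotation) is removed from the list, which is exactly the
situation in which similarity-based enzyme prediction is useful. Note that
absolute scores depend on this package's own fingerprint construction; only
the qualitative ordering is comparable with other tools.

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "derivnet.R", package="derivnet"))') \
    rank --outdir results/
```

Subcommands: `expand` (network JSON + Gephi-compatible GraphML), `rank`,
`pathways --target NAME`, `enzymes --target NAME`, `validate`, `fixtures`.
A YAML config (`--config`) points every stage at user-supplied pathway,
rule, catalog, annotation and reference files; all outputs are deterministic
for a fixed config and seed and carry a config-hash header.

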