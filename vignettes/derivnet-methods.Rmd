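---
title: "Methods: rule-based pathway expansion and enzyme candidate ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based pathway expansion and enzyme candidate ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(derivnet)
```

`derivnet` explores the biochemical vicinity of a heterologous biosynthetic
pathway: starting from the pathway's metabolites it predicts which catalogued
compounds are reachable by plausible enzymatic chemistry, ranks them as
bioproduction targets, and proposes candidate enzymes for the novel reaction
steps. This vignette describes the model underlying each stage, the
parameters that matter, the numerical conventions the implementation fixes,
and what the packaged fixtures do and do not establish about behaviour on
real data.

## Molecules and canonical keys

A molecule is a hydrogen-suppressed colored graph: atoms carry element,
formal charge and an implicit-hydrogen count; bonds carry a Kekulé order and
an aromaticity flag. Implicit hydrogens are completed from a standard valence
model (C 4; N 3, shifted by charge so that N⁺ is tetravalent; O 2; S 2/4/6;
halogens 1), and any structure whose bond orders exceed the maximal valence
is rejected as a chemistry error. Multi-fragment input (salts) is rejected
rather than split, since the expansion operates on single main substrates
with cofactors handled symbolically.

Deduplication across the whole pipeline rests on a **canonical key**: a graph
certificate obtained from a BLISS canonical labelling (via
`igraph::canonical_permutation`) of an auxiliary colored graph in which atoms
are vertices colored by element and charge and each bond is a subdivision
vertex colored by its order — or by a single "aromatic" color when the bond
lies in a perceived aromatic ring, which makes the key invariant under
alternative Kekulé assignments. The key is prefixed with the molecular
formula for readability. Two conventions are fixed repo-wide:

* **Stereochemistry is ignored.** All stereo descriptors (SMILES `@`, `/`,
  `\`, molfile wedges/parities) are stripped at parse time; fixture names
  keep their (S)- prefixes as labels only. The network generator treats
  stereoisomers as one constitution.
* **Aromaticity** is perceived only on six-membered rings of C/N atoms in
  which every ring bond is single or double and every ring atom carries at
  least one double (or input-flagged aromatic) bond. This covers benzenoid
  rings and the pyridinium-type cations that arise from protoberberine
  oxidation. Five-membered heteroaromatics (furan, pyrrole) are treated as
  Kekulé structures, and quinoid rings can in principle be misflagged; the
  BIA chemistry the package ships rules for contains neither case in a
  position where it would change a key.
* **Tautomers and ring–chain forms are not merged**: distinct tautomers get
  distinct keys. This matters for the hemiacetal-series intermediates late in
  the noscapine pathway, which the fixture embeds as their ring-opened
  aldehyde constitutions so that every pathway step is a single subgraph
  rewrite (the cyclic hemiacetal and its open aldehyde would otherwise be
  two nodes connected by no rule).

## Generalized reaction rules

A rule is a bidirectional subgraph rewrite with a third-level EC tag. Each
direction holds a reactive-site pattern (atom constraints on element,
aromaticity, implicit-hydrogen count, charge and degree; bond constraints on
order or aromaticity), an edit script (add/delete atoms and bonds, change
orders and charges), a declared element-count delta for the main substrate,
and a cofactor context — names such as SAM/SAH, O₂, NADPH, acetyl-CoA that
travel on the reaction metadata and are never instantiated as network nodes.
At load time the reverse delta must be the exact negation of the forward
delta; at application time every product is rebuilt from scratch (hydrogen
completion, aromaticity perception, canonicalization) and discarded unless
its element-count change equals the declared delta. Matches that would
violate valence simply produce no outcome, and a rewrite that leaves the
molecule unchanged never forms an edge.

The packaged rule file holds 13 expert-written rules: aromatic
O-methylation, secondary and quaternizing tertiary N-methylation, aromatic
and benzylic hydroxylation, berberine-bridge oxidative C–C cyclization,
methylenedioxy-bridge formation, O-acetylation, acetyl-ester hydrolysis,
oxidative C–N ring cleavage to an aryl aldehyde, oxidative lactonization,
tetrahydroprotoberberine oxidase aromatization, and a decarboxylation that
exists mainly to exercise the CO₂ directionality exclusion. This is a
deliberately small set sufficient for the fixture chemistry — it makes no
claim of parity with comprehensive rule collections, and network sizes
obtained with it are fixture-scale, not literature-scale.

## Network expansion

Expansion is breadth-first by generation. Seeds are generation 0; at
iteration *g* every rule is applied in both directions to every compound not
yet processed, and a product is retained only if it is already in the network
or is a member of some compound catalog (`known_only = TRUE`, the default).
New compounds get generation *g*; a closing pass at the final iteration
records reactions among already-retained compounds without adding nodes.
A **generation therefore counts reaction steps between the seed pathway and
the compound, regardless of the direction in which the rule was travelled**
— a compound first reached by a rule's reverse application (norreticuline,
one demethylation from reticuline) is generation 1.

Edges are normalized to the rule's forward orientation and deduplicated by
the (substrate, product, rule) triple; when two rules produce the same
compound pair, both edges are kept, because enzyme ranking depends on which
reactive site the rule engaged. Each edge stores the reactive-site atoms of
both endpoints and the full cofactor context of both travel directions, so
that pathway search needs no re-matching. Reactions are classified *known*
when the triple (in either orientation) occurs in the reference reaction
database or the compound pair is a seed-pathway reaction; everything else is
*novel*.

The guard of at most 10 generations and the known-compound restriction keep
the expansion bounded; with `known_only = FALSE` the growth is combinatorial
and only small seeds should be used (the test suite uses catechol-sized
molecules for two generations when exercising this mode against a brute-force
enumerator).

Trimming retains exactly the compounds meeting the benzylisoquinoline
composition floor — at least 16 C, 13 H and 1 N, the elemental content of the
1-benzylisoquinoline scaffold — plus the edges with both endpoints retained;
it is idempotent and monotone in the filter thresholds.

## Candidate ranking

Popularity is defined as citations + patents, taken from a packaged
annotation table; the sum is definitional, and rows whose printed source
total disagrees with the sum are surfaced by `validate_annotations()` rather
than reproduced (the fixture contains one such row). Compounds without a
single annotation are excluded, seed metabolites are excluded, ties are
broken by compound name ascending (a documented choice — the source table
never orders ties), and the one-step view keeps generation-1 compounds only.
A live annotation adapter (PubChem/PubMed) is intentionally absent: offline
tables are canonical so that results are reproducible and the test suite
needs no network.

## Pathway search

The reactant–product graph holds one arc per allowed travel direction of
each edge. A direction is excluded when its cofactor context (a) produces
molecular oxygen, (b) consumes CO₂ (reverse decarboxylation), or (c) is a
demethylation converting SAH to SAM — the three categorical directionality
exclusions; no thermodynamic estimation is attempted. Pathways are all
simple (vertex-disjoint) directed paths of length 1..`max_steps` (default 4,
guard 8) from any seed intermediate to the target, enumerated exhaustively
by depth-first search — exact at fixture scale — and ordered by length and
then lexicographically by arc id. Zero-length pathways are not returned, and
pathways differing only in rule assignment over the same compound chain are
kept distinct.

## Reaction fingerprints and enzyme ranking

The reactive site of a reaction is the set of substrate atoms matched by the
rule's pattern plus their images and any introduced atoms on the product
side; for reference reactions it is recovered by re-matching the rule against
the stored substrate and selecting the match that reproduces the stored
product (a consistency error otherwise). The fingerprint collects, for each
depth *d* = 1..7 and each site atom, a canonical descriptor of the atom
environment within *d* − 1 bonds: the atom's label (element, charge,
aromaticity, implicit-H count) plus the sorted distance-tagged labels of the
surrounding atoms, tagged by reaction side. Depth 1 is thus the reactive-site
atoms themselves, and "identical up to seven atoms around the reactive site"
is read as shells of growing bond radius — an interpretation this package
fixes and documents, since atom-count and bond-radius readings are both
defensible. Multi-site reactions combine per-atom features by set union.

The similarity of two fingerprints is the unweighted mean over depths of the
Jaccard overlap of the per-depth feature sets: symmetric, bounded in [0, 1],
exactly 1.0 when the reactions are indistinguishable within the depth
horizon, 0 when no features are shared, and deeper shells never outweigh
shallower ones. Candidate enzymes are reference entries ranked by this score
(sequence-less orphans removed first, ties broken by EC ascending, one best
row per EC class); scores strictly above 0.3 are called significant. A
pathway's enzymatic feasibility is the arithmetic mean of its per-step top
scores, with *known* steps scoring 1.0 by convention — an enzyme is already
assigned to them. Absolute score values are a property of this fingerprint
construction; comparisons with scores from other reaction-similarity tools
are meaningful only at the level of ordering.

## The packaged study system

The fixture pathway runs from (S)-norcoclaurine to noscapine: 17 metabolites
and 17 reactions under 11 distinct rule classes. The published descriptions
of this pathway name the upstream intermediates explicitly but not the full
downstream order or the rule-class assignment, so the fixture embeds a
documented reconstruction: 13 linear steps (O-methylations,
N-methylations, hydroxylations, berberine-bridge closure, methylenedioxy
closure, O-acetylation, oxidative C–N ring opening), then a diamond in which
the final O-methylation and the deacetylation commute on the way to
narcotinehemiacetal, then oxidative lactonization to noscapine. The
reconstruction is internally consistent — every step is regenerated by a
packaged rule, and the element deltas compose from norcoclaurine C16H17NO3
to noscapine's real formula C22H23NO7. Embedded structures are constitutions
only; catalog identifiers are synthetic; and several non-BIA native
substrates in the mini reference database are simplified surrogate
structures, marked as such in their `native_substrate` field.

What the fixtures emulate: catalog-restricted expansion, generation
indexing, one-step derivative recovery (tetrahydropalmatine, armepavine,
laudanine, nandinine at generation 1), popularity ranking with a printed-
total inconsistency, directionality exclusions, orphan-reaction filtering,
and qualitative enzyme ranking (BIA O-methyltransferases outrank non-BIA
ones for the tetrahydropalmatine reaction). What they do not: the scale of
real compound databases and rule collections (thousands of compounds,
hundreds of rules), stereochemical resolution, thermodynamics, or numeric
agreement with published similarity scores. Passing tests therefore
establish the correctness of the machinery, not literature-scale network
statistics.

`random_network()` generates abstract, structure-free networks (seeded, with
a relaxation pass that restores the generation invariant after extra edges
are added) purely for property-style testing of the search layer against
independent oracles.

## Problem sizes and runtime conventions

The test suite and the acceptance script run the full fixture workflow: a
4-generation expansion over 13 rules and ~30 catalogued compounds (seconds),
pathway enumeration on graphs of ≤ ~50 arcs, fingerprinting against a
25-entry reference database, and oracle comparisons on 100 seeded random
graphs of ≤ 12 nodes — sizes chosen so the whole suite runs in a few minutes
on one CPU while still exercising every code path. Workflow outputs carry a
tool-version and config-hash header (never timestamps), so repeated runs
with the same configuration are byte-identical.

## Known limitations

* Rule patterns are structural, not electronic: regioselectivity beyond the
  encoded constraints (e.g. ortho/para preferences of P450 hydroxylation) is
  not modelled, so uncatalogued side products are generated and relied upon
  to be filtered by the known-compound restriction.
* The aromatization rule's reverse direction matches on stored Kekulé
  orders; on molecules parsed from an external Kekulé assignment that
  differs from the one the forward rule produces, the reverse application
  may find no match. Connectivity is unaffected because pathway search
  travels stored edges in both directions.
* Five-membered heteroaromatic perception and charge-separated tautomers are
  outside the fixed aromaticity model.
* The optional live-annotation route described for popularity counts is not
  implemented; annotation tables are file-based by design.
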