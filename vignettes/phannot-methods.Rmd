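---
title: "Cluster-then-transfer annotation of phage proteomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-then-transfer annotation of phage proteomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phannot)
```

## The problem and the strategy

Phage proteomes are dominated by proteins with no detectable sequence
homolog: in mycobacteriophages, roughly two thirds of GFF product fields say
nothing more than "hypothetical protein". Structure comparison is far more
sensitive than sequence comparison at long evolutionary distance, but
predicting a structure for every protein in a pangenome-scale database is
prohibitively expensive. The cluster-then-transfer strategy this package
implements reduces that cost by an order of magnitude:

1. **Cluster** the proteins from pairwise sequence alignments, at high
   identity (50%) and strict bidirectional coverage (90%), so each cluster
   is structurally homogeneous.
2. **Model** only the cluster representatives (done externally; this package
   consumes the per-residue pLDDT confidences stored in the model B-factor
   column).
3. **Search** the representative models against structure databases (done
   externally with a TM-align-mode search; this package consumes the
   tabular hits), pick a best hit per representative, and **transfer** the
   hit's name to every member of the representative's cluster.

Everything expensive — structure prediction, structure search, Pfam/EC
lookup, multimer interaction prediction — enters as files. What this package
owns is the logic between the files: the clustering semantics, the transfer
and its bookkeeping, and the statistics used to audit whether the transfer
can be trusted.

## Clustering semantics

`build_similarity_graph()` turns alignment records into an undirected graph:
a pair qualifies when some record reaches the identity threshold and the
coverage rule. All "set to x" thresholds are **inclusive** (≥), matching the
convention of the alignment tools whose flags they mirror; the strictly
greater-than screens (TM > 0.6 counter-defense, score > 0.8 confidence,
pLDDT > 90 gate, interaction score > 0.5/0.7) are strict because their
sources say "above"/"exceeding".

`greedy_set_cover_cluster()` repeatedly selects the node whose closed
neighborhood covers the most still-uncovered nodes; the selected node
becomes a representative, and it plus its uncovered neighbors form a
cluster. Two design points were genuinely open and are fixed here:

* **Ties** are broken by lexicographically smallest id, everywhere. The
  external tools' internal order is unspecified; determinism is required
  for testing, and any fixed total order is equally defensible.
* An already-covered node may be selected when it still covers uncovered
  neighbors; it then *moves* into the cluster it now represents. This keeps
  the result a partition while following the covering rule literally.
  Candidates must cover at least one uncovered node, which guarantees
  termination.

`reassign_members()` reproduces the reassignment pass of cascaded
clustering: any member without a qualifying edge to its representative is
moved to the lexicographically smallest other representative it does have an
edge to, else becomes a singleton. The operation is idempotent, and the
target choice (smallest qualifying representative) is our decision — only
the existence of the pass is externally specified. Cascaded multi-step
clustering itself is a speed optimization, not a definition, and is
deliberately not reproduced: at desk scale, single-pass greedy set cover
plus reassignment implements the same semantics.

## Annotation transfer and the two rates

A protein is **sequence-unannotated** when its product field is empty or
contains "hypothetical protein" (case-insensitive). A structural hit is a
**void match** when its target name contains any of *putative,
hypothetical, uncharacterized, domain of unknown function* (substring,
case-insensitive; list configurable). The two audited quantities are

* sequence-based rate = (n_all − n_unannotated) / n_all,
* structure-based rate = (n_match − n_void) / n_all,

where n_all counts **all** proteins in the input set, n_match counts
proteins that received a transferred annotation and n_void the transferred
annotations that are void. Using the full protein set as the denominator of
both formulas is the only reading under which the two rates are comparable,
and is the one implemented.

Best hits are selected per query by highest TM-score, then lower E-value,
then database precedence PDB > AFDB_SwissProt > AFDB > other, then target
id. The precedence order is ours: the upstream search runs several databases
without stating a combination rule, and experimentally determined structures
are the natural first choice. Per-phage and per-group rate summaries are
emitted in two labelled variants — unweighted means of per-phage rates and
pooled rates over all proteins of a group — because the published figure
caption does not disambiguate which average it shows.

## Purity and consistency statistics

`structural_purity()` averages LDDT and TM-score over
representative-vs-member alignments per cluster (self-alignments excluded)
and reports medians of the per-cluster means. `pfam_consistency()` scores a
cluster as the mean over **ordered** pairs (reference, other) of
|Pfam(ref) ∩ Pfam(other)| / |Pfam(ref)|: the reference-normalized pair score
is asymmetric, and averaging both directions makes the cluster score
symmetric without discarding the definition. Pfam accessions are compared
as sets. `ec_consistency()` applies the same pairwise scheme to EC codes
truncated at each of the four hierarchy levels, excluding members with
multiple codes entirely and disregarding, per level, codes without a
concrete token there; the score is therefore monotone non-increasing in
level on a fixed member set. Clusters need at least two eligible members to
be scored. `consistency_vs_metric_binning()` uses half-open `(lo, hi]` bins
of the cluster's mean LDDT, matching the interval notation the statistics
are conventionally reported in.

`deepfri_ec_agreement()` compares predicted and reference EC codes on the
first three levels only (top-scoring predictions leave level 4
unspecified), among proteins where both codes are concrete through the
level. `semantic_consistency()` mechanizes the manual equivalence judgment
through a versioned synonym-group config (`inst/extdata/synonym_groups.yaml`
ships a starter set): clusters whose representative's sequence annotation
contains an ambiguous term are removed first, then a member counts as
consistent when its transferred and sequence annotations are identical
after case/whitespace normalization or share a synonym group. Identity is
always a synonym; a missing config is an error rather than silently
identity-only, because the curated groups are part of the method.

## Taxonomy summaries

`lca()` is the deepest node on every input taxon's root path, with depth
measured as root-path length — no majority or weighted variants, for which
there is no evidence in the source method. `rank_distribution()` ascends
items to their ancestor at a rank (default superkingdom), with an
`unassigned` bucket for lineages that never reach the rank (e.g. an LCA at
the root); percentages sum to 100. Both per-query-LCA and raw-best-hit
entry points exist because the published percentages are ambiguous about
which was summarized. A flat top-k rank-by-rank table replaces Sankey
export.

## Interactions

The combined confidence of a predicted complex is 0.8·ipTM + 0.2·pTM.
The screening literature writes the same screen both as "ipTM + pTM > 0.5"
and as this weighted score; the weighted score is the default screened
quantity, with `score_mode = "sum"` available for the raw-sum reading.
Duplicate phage-host pairs (multiple models per pair) collapse to their
maximum score, the usual multimer-ranking convention. Phage nodes carry the
number of proteins their representative stands for; host nodes carry their
degree; heatmap cells are hit counts divided by the number of phages in the
group.

## The synthetic-fixture generator

`generate_fixtures()` plants ground truth for every stage. Sequences are
decorative random strings: no stage of this package computes alignments, so
all pairwise statistics are planted directly in the generated tables.
Defaults encode the study conditions the package targets: 66% hypothetical
products (a ~34% sequence annotation rate), 60% of representatives with a
structural hit of which 10% are void, mean model pLDDT 77, a best-hit
superkingdom distribution of 66.70/15.27/9.78/4.27% (bacteria, eukaryota,
viruses, archaea) with the remainder unassigned, and geometric family sizes
(mean ≈ 2.9) over 60 families — small enough that the full test suite runs
in well under two minutes. Within-family identities (0.60–0.95) lie
entirely above between-family identities (0.05–0.40); this separability is
validated, and makes the planted partition the unique solution at the
default thresholds, so clustering recovery can be asserted exactly.
Planted fractions use deterministic floor rounding with seeded selection,
so rate recovery is exact rather than approximate.

What the generator does **not** emulate: real sequence evolution (identities
are not derived from the sequences), partial-domain alignments, biased
database composition, correlated annotation errors, or model files beyond
CA-only pLDDT tracks. Passing tests therefore certify the logic of the
pipeline, not the biological error rates of the upstream tools.

`expected_values()` returns the exact planted rates, the analytic expected
label consistency π² (an ordered pair agrees only when both members carry
the canonical family label, since decoy labels are member-unique), a 99%
Monte-Carlo interval for the mean cluster consistency averaged over a given
number of seeds, and the expected screened-interaction count with its
binomial standard deviation.

## Numerical and degenerate-input choices

Rates on an empty protein set are an error (undefined), not NaN. Empty or
absent hit names are void; empty products are unannotated. B-factor values
outside [0, 100] are clamped with a warning. pLDDT is read from the CA atom
of each residue, first atom as fallback — the convention of AlphaFold model
files; the upstream description does not state which atom was used, and the
choice only matters for non-CA-uniform B-factors. Bin edges are half-open
on the left; a metric exactly at the lowest edge is outside all bins and
errors. The generator restores the caller's RNG state and uses a single
stated RNG (Mersenne-Twister / inversion / rejection sampling) so fixtures
are byte-stable across sessions.

## Problem sizes used by the tests

The acceptance-style property tests run: exhaustive clustering-oracle
comparison on all 1,024 edge subsets of 5 nodes plus 1,000 random graphs of
up to 8 nodes; 100 perturbed reassignment fixtures; 1,000 random clusters
of up to 8 members for the consistency oracles; 20 seeded fixtures for
exact rate recovery; 1,000 LCA queries over random trees of up to 500
nodes; and 3 × 50 seeded fixtures for the π-recovery check. These sizes
were chosen so the whole suite completes in about two minutes while still
exercising every code path the larger published analysis would.

## Known limitations

* The clustering is single-machine and quadratic in neighborhood scans;
  it is a semantic reference, not a replacement for the prefiltered tools
  at pangenome scale.
* Pfam/EC labels, structure-search hits and interaction confidences are
  trusted as given; no recalibration of E-values or confidence scores.
* Taxonomy reading handles the plain taxdump dialect only (no merged or
  deleted taxid remapping).
* Semantic consistency is only as good as the synonym config; the shipped
  groups are a starter set, not a curated ontology.
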