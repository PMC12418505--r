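---
title: "Scoring, clustering and propagating phosphosite conservation across eukaryotes"
author: "PhosphoCons authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, clustering and propagating phosphosite conservation across eukaryotes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PhosphoCons)
```

## The problem

Most experimentally confirmed phosphorylation sites (phosphosites) come from
human samples; the vast majority of eukaryotic species have essentially no
phosphoproteome annotation. Because phosphosites that matter functionally
tend to be conserved, a reference proteome with well-supported sites can be
used in two directions: to *score* how conserved each human site is across
the tree of life (and read function off the conservation pattern), and to
*propagate* sites onto aligned residues of other species' proteins as
candidate phosphosites.

PhosphoCons implements that pipeline end to end for a reference proteome
with a "gold-standard" site table (sites supported by at least five pieces
of identification evidence, the `min_evidence = 5` default) and a panel of
target proteomes organized into taxon groups.

## The model

### Conservation scoring

For each reference protein we take one candidate orthologue per species (the
top homology hit with E-value at or below `1e-5`; `selectTopHits()`), align
them to the reference, and ask, for every phosphosite, whether the aligned
residue in each species is conserved. Conservation uses the **Ser/Thr
substitution rule**: a site counts as conserved when the aligned residue
equals the reference residue, or when a Thr is aligned with a reference Ser
and vice versa — kinases that target hydroxyl residues typically tolerate
that interchange. The rule never applies to Tyr. Gaps, ambiguity codes (X)
and species with no significant hit all count as *not conserved*, and the
full group is always the percentage denominator, so

\[
\mathrm{percent}_g \;=\; 100 \times \frac{\#\{\text{species in } g
\text{ with a conserved residue}\}}{|g|} .
\]

The species panel defaults to 100 eukaryotes in ten base groups — primates
(18), other mammals (32), birds (12), fish (5), reptiles (4), amphibians
(2), insects/invertebrates (11), fungi (4), plants (7), protists (5) — with
broader unions mammals (50), vertebrates (73) and animals (84). Group sizes
are configurable through `speciesRegistry()`.

The per-site result is a `SiteConservation` object, a
`SummarizedExperiment` with sites as rows, species as columns, and logical
assays `conserved` and `plus1` (the conservation of the residue immediately
C-terminal to the site; `NA` when the site is the reference C-terminus).
Protein-level profiles average the group-percentage vectors of a protein's
Ser/Thr (or, separately, Tyr) sites.

### Alignments

Externally produced alignments load unchanged via `readMsa()`. When only
sequences are available, `buildStarMsa()` produces a reference-anchored star
alignment from pairwise global alignments (BLOSUM62, affine gaps, open 11 /
extend 1). Conservation is only ever read at reference-anchored columns, so
the relative alignment of two *subjects* to each other — the part a
progressive aligner would refine — does not influence any statistic this
package computes.

### Clustering and labels

Proteins (or sites) are clustered by agglomerative hierarchical clustering
on Euclidean distances between raw group-percentage vectors (`complete`
linkage by default; both the linkage and an optional column standardization
are flags, since only the distance is canonical). Clusters are then given
descriptive labels from a template catalog: a template constrains some
groups to **High** (percentage ≥ 75) or **Medium** (≥ 50), thresholds
inclusive. Walking the catalog most-specific-first, a cluster receives the
first label matched by at least 50% of its members; otherwise it is
`"mixed"`. We deliberately do not pick the template with the single largest
matching fraction: any label whose constraints are a subset of a more
specific label's (e.g. "Medium in primates" vs "High in primates") matches
at least as many members by construction, so a largest-fraction rule would
systematically prefer the least informative label. The 50%-majority walk is
also exactly the manual rule the labels mechanize: at least half the
cluster must match the label's description.

Composite labels are defined over base groups ("Medium in vertebrates"
means each vertebrate base group is at Medium), which keeps labels like
"Medium in vertebrates except fish" discriminative.

### Enrichment

Term enrichment per cluster is the one-sided hypergeometric
over-representation test against the background of all analyzed proteins,
with Benjamini–Hochberg adjustment across terms and significance called at
adjusted p < 0.1 (`alpha`). Domain enrichment maps each site to the first
(by file order) InterPro span covering it, then computes, per domain with at
least two mapped background sites,

\[
\text{fold} = \frac{a/b}{A/B},
\]

with `a` pattern sites in the domain, `b` all pattern sites mapped to any
domain, `A` background sites in the domain and `B` all mapped background
sites; reports include log2(fold) and the percentage of pattern sites
mapped (the top-10 by that percentage is the usual display).

### Kinases

Each Ser/Thr site's most likely kinase(s) are the argmax of its score map —
several when tied (`topKinases()`). Kinase conservation is presence of the
species in the kinase's orthologue group, intersected with the registry;
whole groups can be excluded (e.g. birds, whose orthologue annotations can
be systematically incomplete). Site vs kinase conservation is compared by
ordinary least squares on overall percentages (conservation across all
non-excluded species), one pair per tied kinase.

### Propagation

A site is propagated to a species when **both** the residue aligned with
the site and the residue aligned with the reference +1 position are
conserved (S/T interchange allowed wherever the reference residue is S or
T). The +1 residue participates because the position C-terminal to the
phosphoacceptor is central to recognition by proline-directed kinases and
common phosphorylation motifs. Predicted positions are reported in ungapped
target-protein coordinates. Reference C-terminal sites have no +1 residue
to test; they are skipped and reported separately so totals reconcile. The
+1 comparison is made at the reference-anchored column by default; a
`target_adjacent` mode compares the target's own next residue instead (the
two differ only when the target has an insertion immediately after the
site).

Validation against an evidence table reports, per residue class, the
fraction of predictions with any evidence and the fraction of evidenced
predictions with strong evidence (count ≥ `min_strong`, default 5). The
enrichment factor divides the evidence rate among predictions by the
evidence rate expected when picking S/T/Y residues of the target proteome
uniformly at random.

## The synthetic-data generator

`simulateStudy()` builds a complete, truth-annotated study so every stage
is testable without any downloads:

* Reference proteins of 120–240 residues with 2–5 phosphosites each
  (the gold-standard set averages 3.6 sites per protein), residues drawn
  S:T:Y at 16978:2747:986 — the composition of the gold-standard set.
* Four default archetypes of 50 proteins each plant the main conservation
  patterns: high in all species, high in vertebrates & invertebrates, high
  in primates, medium in vertebrates except fish. Per species and site, the
  site and +1 columns mutate to a *non-conserving* residue with the
  archetype's per-group probability (0.02–0.04 for High groups, 0.30 for
  Medium, 0.90 for non-conserved groups, 0.95 for fish in the except-fish
  archetype); conserved S/T columns are emitted as the other hydroxyl
  residue 15% of the time to exercise the substitution rule; background
  positions mutate at 5%. The High/Medium probabilities are chosen so the
  planted group percentages sit well inside the ≥75 / ≥50 label bands even
  for the smallest groups (amphibians has two species, so a single
  non-conserving draw costs 50 points).
* Within-archetype noise is one uniform ±10-point shift per protein applied
  to all groups, modelling proteins that are globally somewhat more or less
  conserved than their archetype.
* 2% of species per protein are decoys: they get no alignment row,
  emulating queries with no significant hit, and count as not conserved.
* Annotation maps plant term enrichments (by default one 4-fold, 20-protein
  term per archetype) next to uniformly drawn null terms.
* The evidence table for the validation species covers true propagated
  sites at the reported mouse rates — 82% of Ser/Thr and 75% of Tyr
  predictions evidenced, 61% of evidenced sites strong — plus background
  evidence on other S/T/Y residues at 5.9% (with 20% strong), the rates
  implied by comparing those coverages with the published 14x/43x
  enrichment-over-chance estimates.

A single integer seed drives the generator; per-protein substreams are
derived by stable hashing of the accession, so enlarging a study never
perturbs previously generated proteins, and identical configurations are
byte-reproducible.

**What the generator does not emulate:** phylogenetic correlation between
related species (flips are independent given the group probability), indel
evolution, alignment error, compositional bias, and the sparsity of real
proteomes (planted sites are dense relative to a real proteome, which
compresses enrichment factors computed on synthetic bundles: the predicted
sites themselves make up a visible share of all S/T/Y residues and inflate
the background evidence rate). Passing tests therefore demonstrate the
statistics and the plumbing, not performance on real alignments.

## Numerical choices and degenerate inputs

* Positions are 1-based inclusive everywhere; MSA columns are 1-based.
* Residues are uppercased on read; X never counts as conserved.
* The Welch (unequal-variance) two-sample t test is used for group
  comparisons; with two identical constant arms the comparison degenerates
  and is reported as t = 0, p = 1.
* Tukey box statistics: whiskers reach the farthest data point within
  1.5 × IQR of the box.
* Disorder calls use a strict threshold: score > 0.5 is disordered.
* Ties in top-hit selection break by bit score, then input order; ties in
  kinase matching keep all argmax kinases; ties in labeling resolve by
  catalog order.
* `k` for clustering defaults to 10 (per residue class, Ser/Thr and Tyr
  clustered independently); the desk-scale analyses in the tests use
  `k = 4` to match the four planted archetypes.
* Empty site tables, clusters with no mapped sites, and missing optional
  inputs (annotation, InterPro, kinases, evidence) degrade to empty or
  skipped outputs, never to errors; genuinely malformed inputs fail fast
  with the offending path or record named.

## Problem sizes used in tests

The packaged checks run on desk-scale data chosen to keep the whole suite
fast while leaving no statistic untested: 200-protein bundles (4 archetypes
by 50 proteins, around 700 sites against 100 species) for the end-to-end
recovery checks, 200 randomized alignments for the scorer-vs-oracle
equivalence, exhaustive enumeration for every hypergeometric universe up to
N = 12, and 10,000-draw calibrations for the enrichment factor. The same
code paths accept full-scale inputs (thousands of proteins, alignments read
from a directory) unchanged through `runConservationStudy()` /
`runPropagationStudy()`.

## A worked example

```{r example, eval = FALSE}
cfg <- simulationConfig(seed = 1, archetypes = standardArchetypes(50))
bundle <- simulateStudy(cfg)

sc <- profileSites(bundle$msas, bundle$sites, bundle$registry)
pp <- proteinProfiles(sc, "ST")
cl <- labelClusters(clusterProfiles(pp, k = 4), pp)
table(cl$labels[as.character(cl$assignments)],
      bundle$archetype[rownames(pp)])

pred <- propagateSites(bundle$msas[[1]],
                       bundle$sites[bundle$sites$accession ==
                                      names(bundle$msas)[1], ],
                       bundle$registry)
head(pred$predictions)
```

`scripts/acceptance.R` runs exactly this study end to end and prints the
recovered label accuracy, planted-enrichment detection, validation
percentages and enrichment factors.

## Known limitations

* The star alignment is a stand-in for a progressive aligner; for exact
  reproduction of externally computed results, load the original
  alignments.
* Kinase orthologue groups are consumed as tables; motif scores are not
  recomputed.
* Only S/T/Y sites are handled; propagation of other phosphoacceptors is
  out of scope.
* Site-level clustering reuses the protein-level machinery on site
  profiles; no site-specific distance is implemented.
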