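# PhosphoCons

Conservation analysis and cross-species propagation of phosphorylation
sites.

Most experimentally confirmed phosphosites come from human data; nearly all
other eukaryotes have sparse or absent phosphoproteome annotation. Because
functionally relevant phosphosites tend to be conserved, a well-annotated
reference proteome can be leveraged in two directions, and this package
implements both as a reusable pipeline for computational biologists working
on PTM annotation and molecular evolution:

1. **Score** the conservation of each reference phosphosite (Ser/Thr/Tyr)
   across species groups, cluster proteins by their conservation-pattern
   vectors, attach descriptive High/Medium labels, and test clusters for
   functional-term and protein-domain enrichment, plus the conservation of
   each site's most likely kinase.
2. **Propagate** phosphosites onto aligned residues of target-species
   proteins and validate the predictions against independent evidence
   tables.

## The statistics at the core

For a site *s* and species group *g* the conservation percentage is

    percent(s, g) = 100 * |{ species in g with a conserved aligned residue }| / |g|

where a residue is conserved if it equals the reference residue or if both
are in {S, T} (the Ser/Thr substitution rule; never applied to Tyr); gaps,
X, and species without a significant homology hit (E-value ≤ 1e-5) count
as not conserved. A site is **propagated** to a species when the residues
aligned with both the site and its +1 neighbor are conserved. Cluster
enrichment is the hypergeometric upper tail P(X ≥ k) for k annotated
proteins in a cluster of n drawn from N background proteins with K
annotated, BH-adjusted (significant at adjusted p < 0.1). Domain fold
enrichment is (a/b)/(A/B) over sites mapped to domains by the first-match
rule. Prediction validation reports the evidence rate among predictions and
its enrichment factor over picking S/T/Y residues at random.

A deterministic synthetic-data generator (`simulateStudy()`) plants
conservation archetypes, term enrichments and evidence tables with known
truth, so the entire pipeline is testable offline.

## Worked example

```r
library(PhosphoCons)

cfg    <- simulationConfig(seed = 1, archetypes = standardArchetypes(10))
bundle <- simulateStudy(cfg)

sc <- profileSites(bundle$msas, bundle$sites, bundle$registry)
sc
#> SiteConservation: 135 sites x 100 species (13 groups)

pp <- proteinProfiles(sc, "ST")
round(head(pp[, c("primates", "other_mammals", "fish", "fungi", "plants")], 3), 1)
#>         primates other_mammals fish fungi plants
#> SIM0001     94.4          87.5  100  87.5   85.7
#> SIM0002     83.3          96.9   90 100.0   85.7
#> SIM0003     91.7          92.2  100  87.5  100.0

cl <- labelClusters(clusterProfiles(pp, k = 4), pp)
table(planted = bundle$archetype[rownames(pp)],
      label   = cl$labels[as.character(cl$assignments[rownames(pp)])])
#> every planted archetype lands in its own cluster with the planted label:
#> 10/10 "High in all species", 10/10 "High in primates",
#> 10/10 "High in vertebrates & invertebrates",
#> 10/10 "Medium in vertebrates except fish"

acc <- names(bundle$msas)[1]
pred <- propagateSites(bundle$msas[[acc]],
                       bundle$sites[bundle$sites$accession == acc, ],
                       bundle$registry)
head(pred$predictions, 3)
#>    species_id           accession position residue plus1_residue ...
#> 1 primates_01 SIM0001_primates_01       58       S             T
#> 2 primates_02 SIM0001_primates_02       58       S             T
#> 3 primates_03 SIM0001_primates_03       58       S             T
nrow(pred$predictions)
#> [1] 170
```

The first rows of `pp` are group-percentage vectors (percent of each
group's species in which the protein's Ser/Thr sites are conserved, missing
orthologues counted as not conserved). The cross-table shows the planted
conservation archetypes recovered by Euclidean clustering plus majority
labeling. The prediction table gives target-coordinate phosphosite
candidates — here human-site 58 of the first simulated protein propagates
to 170 species × site combinations, some through the Ser→Thr substitution
(`residue = T` would appear where the target carries Thr).

For file-based studies, `runConservationStudy()` and
`runPropagationStudy()` orchestrate the same stages from FASTA/TSV inputs
to TSV outputs (site and protein conservation tables, labeled clusters,
term/domain enrichment, kinase conservation, predictions, per-group
summaries, validation) with a JSON manifest of parameters and input
checksums.

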