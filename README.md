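# adhesomics

Quantitative analysis of integrin activation state-dependent adhesion
complexes and of microtubule cortical targeting.

Integrins switch between active (ligand-binding) and inactive
conformations, and the protein complexes they nucleate differ between the
two states. `adhesomics` implements the downstream analysis of a label-free
affinity-purification mass-spectrometry comparison of the two complex
types, together with the cell-biological quantifications that such a
comparison motivates:

* **Spectral-count quantification.** Raw spectral counts SpC are converted
  to normalized spectral counts, `NSC = SpC / (T_s × M)` with `T_s` the
  run's total spectra and `M` the protein's molecular weight (kDa);
  technical replicates are summed within each biological isolation and
  biological replicates averaged per condition. Fold enrichment is the
  active/inactive ratio of mean NSC, with a `unique` sentinel for proteins
  detected in only one state. Differential flags come from a
  negative-binomial exact test (edgeR) at 5% Benjamini–Hochberg FDR.
* **Profile clustering.** Hierarchical clustering of per-replicate NSC
  profiles under the uncentred Pearson similarity
  `r = Σxy / √(Σx²·Σy²)` with complete linkage; clusters are the maximal
  subtrees with all node similarities `r ≥ 0.80`, labelled
  active/inactive/unenriched by their median log2 fold change.
* **Interactome hop analysis.** A merged, self-loop-free, undirected
  protein–protein interaction graph with breadth-first hop distances from
  a seed integrin (ITGB1), functional-class coverage summaries, and
  neighbourhood-intersection candidate screens.
* **Overrepresentation statistics.** One-sided Fisher (hypergeometric
  tail) and conservative EASE scores per annotation term, keyword-style
  filtering (fold enrichment ≥ 1.5, Bonferroni P < 0.05, EASE < 0.05, ≥ 2
  proteins), a 100-randomization resampling FDR, and a fold-change
  annotated enrichment map (terms × proteins) clustered like the protein
  profiles.
* **Cortical microtubule dynamics.** Peripheral 5 × 2 μm box densities
  around a cell-boundary polygon, micropattern patch quantification
  (2 μm discs on a 9 μm square lattice, rolling-ball background
  subtraction), per-frame tip-to-edge distances, cortical residence
  lifetimes (longest run within 2 μm of the edge at 10 s frames),
  displacement/growth-excursion summaries and positive-signal area
  fractions.

Every input has a synthetic generator (`sim_counts()`,
`sim_interactome()`, `sim_annotations()`, `sim_tracks()`,
`sim_pattern_image()`) that plants known structure, so the whole pipeline
is testable end to end without external data.

## Worked example

```r
library(adhesomics)

## simulate a 2-condition, 2x2-replicate experiment with planted enrichment
cfg <- sim_count_config(n_proteins = 500, baseline_mean = 50,
                        planted_fold = 4, frac_active_enriched = 0.1,
                        frac_inactive_enriched = 0.1, seed = 7)
sim <- sim_counts(cfg)

keep <- filter_min_count(sim$counts)              # total SpC >= 4
nsc  <- compute_nsc(sim$counts[keep, ], sim$design, sim$meta)
agg  <- aggregate_replicates(nsc, sim$design)
quant <- fold_enrichment(agg$condition_mean)

planted <- sim$truth$accession[sim$truth$class == "active_enriched"]
median(quant$fold[quant$accession %in% planted], na.rm = TRUE)
#> [1] 3.972668

## cluster profiles and label enrichment direction
tree <- hclust_profiles(profile_matrix(agg$bio))
asg  <- label_clusters(extract_clusters(tree, r_min = 0.80), quant)
table(asg$label[match(planted, asg$accession)])
#>     active unenriched
#>         49          1

## the packaged +TIP registry summary
unlist(summarize_tips(tip_registry()))
#> n_known  n_identified  pct_of_known  pct_above_threshold
#>      31            15            48                   73
```

The planted fourfold enrichment is recovered (median estimated fold 3.97),
and 49 of the 50 planted active-enriched proteins land in active-labelled
clusters. The packaged registry of known microtubule plus-end tracking proteins
gives 15 identified (48% of the known family), 73% of them more than
twofold enriched in active-integrin complexes.

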