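# cogevol

Comparative evolution of a transcription-factor gene family across six
dicot and five grass genomes, as a tested, reusable R pipeline.

Plant transcription-factor families (the motivating case is the NAC
family, NAM/ATAF/CUC) expand and contract dramatically across flowering
plants. Asking *how* — which duplications are ancient (pre-dating the
radiation of dicots or grasses) versus recent and species-specific, how
many genes the common ancestors carried, and whether selection pressure
differs between the dicot and grass copies — requires a chain of
analyses: orthology clustering, per-cluster phylogenies, gene-tree /
species-tree reconciliation, and codon-model tests of selection.
`cogevol` implements that chain end to end, together with a
synthetic-data generator that produces gene families with *known* event
histories and selection regimes, so every stage can be validated by
recovery of planted truth.

## What the package computes

- **Filtering** — removes CDS shorter than 400 nt and collapses putative
  alleles: same-species pairs whose optimal global alignment is gap-free
  with nucleotide identity > 95%.
- **COGs from BeTs** — all-against-all Smith–Waterman protein similarity
  (BLOSUM62, affine gaps), best hits (BeTs) per gene and foreign species,
  and Clusters of Orthologous Groups built by merging triangles of
  reciprocal BeTs that share an edge; asymmetric-only genes attach as
  satellites.
- **Phylogenies** — alignment columns are filtered by a 0–100
  conservation score (threshold 12); trees are neighbor-joining on
  pairwise maximum-likelihood JTT distances, with column-resampling
  bootstrap supports.
- **Duplication/loss inference** — minimize-duplication rooting, LCA
  reconciliation, classification of duplications as pre-split,
  ancient-dicot/grass or recent (≤ 2 species), loss calling both by the
  subgroup-absence rule and by reconciliation, and ancestral copy-number
  profiles obeying `count(child) = count(parent) + gains − losses` on
  every branch.
- **Selection** — pairwise dN/dS by Nei–Gojobori counting and by ML under
  the GY94 codon model

  `q_ij = π_j · κ^[transition] · ω^[nonsynonymous]` (single-nucleotide
  changes only, matrix scaled to one expected substitution per codon),

  with saturated pairs (dS > 2) discarded; one-ratio vs branch (k-ratio)
  models with LRTs; the M3 three-class site mixture; and the
  Markov-modulated M3+S1 model in which a site's ω class switches along
  branches at rate δ (pruning over the expanded 183-state space), with
  naive-empirical-Bayes partitioning of positive sites into dicot- and
  grass-specific lists.

## Worked example

```r
library(cogevol)

st  <- build_default_species_tree()          # 6 dicots + 5 grasses
cfg <- sim_config(lambda = 0.1, mu = 0.05, n_codons = 200, seed = 7)
fam <- simulate_family(st, cfg)              # birth-death gene history
head(fam$events)
#>         event species_branch_child       time gnode observable
#> 1 duplication                   13 0.32230733     2       TRUE
#> 2 duplication                    1 0.76641508     6       TRUE
#> 3 duplication                    3 0.30334773    12       TRUE
#> 4        loss                    9 0.05855742    34      FALSE
#> 5 duplication                   10 0.58738918    36       TRUE

rec <- reconcile(fam$tree, st)               # LCA reconciliation
rec$n_dup                                    # duplications recovered
#> [1] 4
prof <- reconstruct_copy_numbers(list(rec), st)
subset(prof$counts, label == "MRCA_dicot")   # ancestral copy number
#>    node      label count
#> 13   13 MRCA_dicot     2
```

The event table above is the planted truth: four observable duplications
(the fifth event is a loss whose lineage left no descendants, hence
unobservable). `reconcile()` recovers all four from the pruned gene tree
alone, and `reconstruct_copy_numbers()` turns the reconciliation into
per-node ancestral counts — here two copies already present in the dicot
ancestor — and per-branch gains/losses.

A full synthetic analysis — simulation, filtering, COGs, trees, events,
selection, report — lives in the numbered scripts under `analysis/`
(shared settings in `analysis/config.yaml`):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_filter_cogs.R
# ... through
Rscript analysis/06_report.R
```

Stage outputs and the final report tables (duplication/loss summary,
branch-model table, site-model table, copy-number profile) are written
under `results/analysis/`.

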