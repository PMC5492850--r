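---
title: "Models and methods behind cogevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cogevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`cogevol` analyzes the evolution of a transcription-factor gene family
across six dicot and five grass genomes: orthology clustering, per-cluster
phylogenies, duplication/loss inference with ancestral copy numbers, and
codon-model tests of selection. This vignette is the package's own account
of the models it implements, the choices made where the design was open,
and what the synthetic-data validation does and does not establish.

## The reference species tree

All analyses are framed by a fixed rooted 11-taxon species tree:
dicots ((Ath,Bra),((Gma,Mtr),(Ptr,Rco))) and grasses
((Bdi,Osa),(Sit,(Sbi,Zma))), joined at the root, following accepted
angiosperm relationships. Branch lengths default to 1 in abstract time
units; nothing in the package interprets them as absolute divergence times
(the dicot/grass split is often quoted near 145 Mya, but no calibration is
attempted, and simulator time is unitless).

## Synthetic data: what it emulates

The generator is first-class, tested code, because every downstream stage
is validated by recovering its planted truth.

**Gene family histories.** Gene lineages travel down the species tree;
each lineage duplicates at rate λ and dies at rate μ (a linear
birth–death process simulated by exponential waiting times), and at each
speciation node every live lineage enters both daughter branches. The
full event log is kept, including events on subtrees that later went
extinct; a duplication is flagged *observable* when both daughter
lineages left extant descendants, and per-branch *observable losses*
count surviving speciation lineages whose daughter in one branch died
out, restricted to branches inside the species subtree spanned by the
surviving family — a loss outside that frame (say, a whole partition
going extinct) leaves no trace in the pruned tree, so no inference
method can see it. Only observable truth is used when scoring
inference. Defaults λ = 0.1,
μ = 0.05 per lineage per unit time give desk-scale families (roughly
1–3 genes per species on the default tree) with a realistic mixture of
duplications and losses. An explosion guard aborts a branch whose
cumulative lineage count exceeds 10,000.

**Codon alignments.** Sequences evolve under the GY94 codon model: the
61×61 rate matrix has `q_ij = 0` for multi-nucleotide changes and
otherwise `π_j`, multiplied by κ for transitions and ω for nonsynonymous
changes. Regimes: one-ratio; branch-specific ω (dicot/grass/other edge
classes); the M3 three-class site mixture; M3+S1, simulated on the
expanded class×codon state space so class switches along branches are
part of the recorded truth; and a planted branch-site scenario (chosen
sites positively selected on chosen branches only) used to exercise
clade-specific site detection. Matrix scaling mirrors the corresponding
likelihood model exactly: branch models scale each class's matrix to one
expected substitution per codon on its own; site-mixture models share a
single mixture scaling across classes (the standard convention, and the
one under which M3+S1 with δ = 0 reduces to M3); the branch-site
scenario anchors scaling to the purifying background class. Codon
frequencies default to F3x4 from uniform nucleotide composition; the
standard genetic code is fixed and stop codons are never sampled.
Alignments are simulated gap-free — indel simulation is out of scope, so
the column-score filter is exercised on hand-built alignments instead.

**Planted artifacts.** Allele-like copies are indel-free point-mutated
duplicates at a configured identity (default 97%, third positions
preferred so the copy stays sense); fragments are in-frame truncations
below a configured length (default 300 nt). These exist solely to give
the filters something to catch.

What passing these tests shows about real data is limited: the generator
has no alignment error, no indels, no assembly artifacts beyond the
planted ones, no rate heterogeneity beyond the modeled regimes, and no
genome-scale complexity. Recovery rates reported by the acceptance
checks are properties of the method under the stated model, not field
performance guarantees.

## Filtering and orthology

Sequences shorter than 400 nt are removed. Putative alleles are
same-species pairs whose *optimal* global nucleotide alignment contains
no gaps and exceeds 95% identity; each allele-connected component keeps
its longest member (ties: lexicographically smallest id). Candidate
pairs are pre-restricted to length differences ≤ 5%, since an indel-free
alignment of very unequal sequences cannot reach the cutoff.

Similarity scoring is full Smith–Waterman on proteins with BLOSUM62 and
affine gaps (open 11, extend 1) — desk-scale families do not need
heuristics, and this removes the external search-tool dependency; a
blast outfmt-6 table can be ingested instead for larger runs. For each
gene and each foreign species the best hit (BeT) is the top score, ties
broken by percent identity then lexicographic id (the tie-break is this
package's choice). COGs are triangles of reciprocal BeTs spanning three
species, merged transitively while sharing an edge. Genes attached only
by asymmetric edges become flagged satellites and are excluded from
downstream trees by default; their treatment in clustering diagrams of
this kind is traditionally ambiguous, so the package makes the exclusion
explicit and configurable. Whether BeTs should come from protein or
nucleotide scores is also ambiguous; protein scoring is used since the
search databases in such studies are protein-coding transcript sets.

## Alignment quality and trees

The per-column conservation score is a documented reimplementation
choice: the mean BLOSUM62 score over all residue pairs in the column
(gap-containing pairs contribute the matrix minimum), rescaled linearly
so the matrix minimum is 0 and the maximum (W/W) is 100. Columns scoring
strictly above 12 are retained — the conventional cutoff, but on this
package's own documented scale, since the internal score of the original
alignment viewer is not recoverable from published text. The kept-column
index map is returned for codon back-mapping and site reporting.

Distances are pairwise maximum-likelihood under JTT (published
exchangeabilities and stationary frequencies, matrix normalized to one
expected replacement per site), with gapped sites deleted pairwise —
pairwise deletion preserves signal in sparse cluster alignments. The 1-D
likelihood in t is maximized by bracketed search on [1e-6, 50] (tolerance
1e-8); pairs whose optimum sits at the bound are set to 50 and flagged
saturated. Trees are canonical Saitou–Nei neighbor joining; negative
branch estimates are clamped to zero and flagged. Bootstrap resamples
columns with replacement, rebuilds distance matrix and tree per
replicate, and reports bipartition percentages on the full-data tree;
everything is deterministic given the seed. Maximum-likelihood tree
search is intentionally not implemented: NJ is the corroborating method
in the motivating study and the two approaches agreed there.

## Reconciliation and event classification

Each rooted gene tree is mapped onto the species tree by LCA
reconciliation; a node is a duplication iff it maps to the same species
node as one of its children. Implied losses are placed on species
branches: when a lineage maps from node *a* down to descendant *d*, each
intermediate species node contributes a loss on its off-path daughter
branch, and for a duplication the node *a* itself is passed as well.
Exhaustive enumeration over all ancestor-consistent mappings (feasible
for small trees) is used in the test suite to confirm both the
duplication counts and the dup+loss totals are minimal.

Rooting defaults to minimize-duplication: every edge of the unrooted
tree is tried, the edge minimizing duplications + losses wins, ties
prefer a root separating dicots from grasses cleanly, then the smallest
leaf id. Midpoint and explicit-outgroup rooting are available; outputs
record the method used.

Duplications are classified by their mapped node: the species root gives
*pre-split*; within a partition, a duplication spanning at most 2 extant
species is *recent* (the notion "one or few closely related species"
needs a number; 2 is the default and is configurable), otherwise
*ancient*. Losses are reported two ways, labeled by method: the
subgroup-absence rule (each partition species missing from a dicot/grass
subgroup is one loss) feeds the per-COG summary table, while
reconciliation losses feed the copy-number profiles — the two notions
genuinely differ when a whole subgroup is missing, so both are kept.
Each reconciliation duplication node is counted separately; a manual
count might merge adjacent events, so this convention is stated
explicitly. Low-support subgroups trigger a warning but are used; no
collapse rule is applied.

Copy-number profiles sum reconciliations over COGs: a COG contributes
one lineage at its mapped origin (entering as a gain on the branch into
that node when the origin is below the species root, so the balance
`count(child) = count(parent) + gains − losses` holds on every branch by
construction), duplications add gains on the branch into their mapped
node, and reconciliation losses subtract. Leaf counts are cross-checked
against the genes actually present; any mismatch is an internal error.

## Codon models and fitting

Pairwise dN/dS is available two ways. The counting estimator (NG86)
enumerates single-nucleotide mutations per codon for site counts
(mutations to stops are excluded from numerator and denominator),
averages observed differences over all minimal mutational paths that
avoid stops, and applies the Jukes–Cantor correction; it doubles as the
independent oracle for the ML estimator, and its equal-path weighting is
only consistent without transition bias, so convergence checks simulate
at κ = 1. The ML estimator maximizes the two-sequence GY94 likelihood
over (t, κ, ω), seeded from the counting estimates; dN and dS are
decomposed from t via the fitted matrix's nonsynonymous/synonymous flux
fractions with site proportions from the same matrix at ω = 1, so
dN/dS = ω̂ exactly. Counting-saturated pairs short-circuit to a flagged
infinite-distance result, and fitted pairs at the t or ω bounds are
flagged saturated; within-subgroup comparisons additionally discard
pairs with dS > 2.

Subgroup means are compared with a two-sided Mann–Whitney U test (exact
for small tie-free samples). Pairwise ω values within a subgroup share
sequences and are not independent; results carry an explicit caveat
flag, and a one-pair-per-gene subsampling option is provided.

Likelihood fits run Felsenstein pruning over the 61 codon states (183
for the switching model) with per-node rescaling. Parameters are
log-transformed (mixture weights as logits, ω classes as ascending
increments for identifiability) and optimized by bounded L-BFGS-B;
convergence uses the optimizer's relative-tolerance control, and
jittered restarts are available via `restarts` (the default is a single
well-initialized run — alternative fits are seeded from their nested
null's optimum, which both speeds convergence and guarantees the lnL
nesting chain up to optimizer tolerance). Branch lengths can be
optimized jointly (`branch_mode = "joint"`, the branch-model default),
rescaled by a single factor from the input tree (`"scale"`, the
site-model default — one global rate parameter over NJ-quality input
lengths, the classic shortcut for mixture models whose branch-length
surface is expensive), or held fixed. κ is estimated jointly and shared
across classes and branches. Codon frequencies default to F3x4 estimated
from the data.

M3+S1 places the site process on the class×codon state space: within a
class the class's GY94 matrix applies; between classes the codon is
unchanged and the switch rate from class k to l is δ·p_l — a single
switching parameter with jump rates proportional to the stationary class
weights, which keeps the chain reversible with stationary distribution
p_k·π_c. The generator is checked to have zero row sums, and the whole
matrix shares the mixture scaling, so δ = 0 reproduces M3 exactly. With
this parameterization M3+S1 adds one free parameter over M3, so the LRT
defaults to df = 1; published analyses of this model pair have reported
df = 2 under a richer switching parameterization, and since the original
accounting is not recoverable, the df is exposed as an override rather
than guessed. Per-site class posteriors at every node come from the
standard up/down (inside/outside) pass; a site is called dicot-specific
when the mean posterior of the top-ω class over dicot-subtree branches
(evaluated at each edge's child node) exceeds 0.5 while the grass mean
does not, and vice versa; sites exceeding both thresholds are listed as
shared. Sites are reported in original-alignment coordinates whenever a
kept-column map is supplied.

## Numerical choices and degenerate inputs

Reversible rate matrices are eigendecomposed via the symmetrized form
`D^{1/2} Q D^{-1/2}`; transition probabilities are clipped at zero and
renormalized by row to absorb roundoff. Pruning rescales partial
likelihoods by column sums per node. Identical sequences yield distance
0 and an undefined ω (flagged, never 0/0); all-gap bootstrap pairs skip
the replicate with a warning when more than 1% are lost; empty COG lists,
empty event tables and all-tied rank tests all return well-defined
degenerate outputs (empty report, all-zero summary, p = 1).

## Validation design and problem sizes

The acceptance suite checks recovery properties, not printed numbers from
any genome-scale study — those depend on eleven full genome releases and
are out of reach at desk scale. Sizes used by the default suite:
orthology recovery over 50 single-copy families; filter recall over 20
seeds with paralogs planted at ≥ 10% divergence; reconciliation equality
with the exhaustive-map oracle on random gene trees of 3–7 leaves against
a 4-taxon species tree (the oracle enumerates every valid mapping, so
oracle tractability caps the tree sizes; gene trees are sampled rather
than enumerated exhaustively over all labelings); duplication/loss
recovery over 300 simulated histories per regime; one-ratio ω recovery
(ω = 0.15, 500 codons, 11 taxa, 20 seeds) and two-ratio ordering
(ω = 0.1 vs 0.3, 300 codons, 50 seeds); LRT calibration over 200 null
replicates at 100 codons on a 4-taxon subtree; switching-model detection
with 10 planted grass-branch positive sites in 600 codons on the full
11-taxon tree over 6 seeds; and NJ topology recovery over 100 replicates
at 2,000 amino-acid sites. The two-ratio recovery scenario — grass
branches at ω = 0.3 against dicot branches at ω = 0.1 — is the
recoverable analogue of the faster-grass-evolution pattern the pipeline
is designed to detect.

## Known limitations

No indel or alignment-error model; NEB (not BEB) site identification;
a single shared κ; one switching parameter with weight-proportional
jumps rather than a general switching matrix; probabilistic
reconciliation and rearrangement of weak edges are out of scope; the
subgroup-mean comparison inherits the non-independence of pairwise ω
values noted above.
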