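---
title: "Methods: pan-genome structure, openness and phylogenetic incongruence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome structure, openness and phylogenetic incongruence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`panevo` implements a desk-scale bacterial pan-genome analysis: from
genome-tagged gene sequences to ortholog clusters, occupancy tiers,
accumulation curves with a Heaps'-law openness fit, ANI-based species
clustering, per-gene trees ranked against a reference, consensus SNP
calls, a horizontal-gene-transfer screen, and accessory-genome
enrichment. Because real multi-genome datasets are too heavy for a test
suite, the package ships a simulator that generates multi-species
pan-genomes with fully recorded ground truth; every stage is validated
against that truth or against independent brute-force oracles. The
`analysis/` scripts run the whole workflow on a reference simulation and
write their tables under `results/`.

# The simulator

`sim_config()` describes a dataset of `n_species` clades with
`genomes_per_species` genomes each (default 4 × 8, the shape of a typical
multi-species genus panel). Gene families are of two kinds:

* **core** families, carried by every genome (default 600);
* **accessory** families (default 1200), each carried by an i.i.d.
  Bernoulli draw of genomes at `accessory_presence_prob` (default 0.3).
  Half of the accessory families (`clade_restricted_frac = 0.5`) are
  restricted to one randomly chosen species clade, which is the simplest
  mechanism that yields shell and cloud occupancy tiers *and*
  species-specific accessory sets for the enrichment stage.

Sequences evolve from a uniform-random ancestral gene along a two-level
species tree (root → species ancestor → genome tip) under Jukes–Cantor
substitution: every site changes with probability
$\tfrac{3}{4}(1 - e^{-4d/3})$ on a branch of length $d$, uniformly to one
of the other three bases. There is **no indel process**: all copies of a
family are equal-length and positionally homologous. This keeps cluster
alignments trivial and SNP semantics unambiguous, and it is the one
feature of real data the simulator deliberately does not emulate — a
green test suite says nothing about gap handling on real genes beyond
what the center-star unit tests cover.

Divergence defaults are set once from the Jukes–Cantor identity
$I(d) = \tfrac14 + \tfrac34 e^{-4d/3}$: within-species pairwise divergence
0.046 substitutions/site gives $I \approx 95.5\%$ (the conventional
95–96% ANI band for conspecific bacteria), and between-species divergence
0.085 gives $I \approx 92\%$, comfortably below the 95% species cutoff
but close enough that species discrimination is non-trivial. Branch
lengths receive a mild multiplicative jitter (uniform 0.8–1.2) so
realized divergences vary; the realized branch lengths are recorded in
the truth object and all calibration checks are made against them, not
against the nominal values. These values are a calibration to the ANI
band, not a claim about any particular genus' biology.

`plant_hgt()` replaces a recipient genome's copy of a core family with a
fresh re-evolution of a cross-clade donor's copy at within-species
divergence — the transferred gene therefore looks like a member of the
donor clade, which is the signature the detector screens for. An event
list with donor/recipient genomes and species is appended to the truth.

# Ortholog clustering

`align_pair()` is an end-to-end Needleman–Wunsch alignment (match +1,
mismatch −1, gap −2 by default — simple unit-cost scores appropriate for
within-genus DNA). Identity is matches over aligned columns; coverage is
both-aligned columns over the shorter sequence's length.

`cluster_genes()` joins gene pairs with identity ≥ 70% and coverage
≥ 75% (the documented defaults of common pan-genome clustering tools;
the original OrthoMCL-style BLAST + Markov-clustering pipeline is
deliberately replaced by this deterministic, dependency-free procedure)
and reports connected components — single linkage. Two performance
shortcuts leave the components provably unchanged:

* a pair whose members are already in one component is never aligned
  (an intra-component edge cannot change connected components);
* above 64 genes, candidate pairs are pre-screened for ≥ 2 shared
  11-mers at identical positions (sampled every 4 bp). This positional
  screen leans on the no-indel, equal-length family design; on real
  genes with indels it would under-join, so it is switchable
  (`prefilter = "none"`) and off by default for small inputs, where the
  brute-force oracle tests compare against the full graph.

The alignment kernel is C++; long comparisons run inside a ±40-column
band, which is exact whenever the optimal path stays in the band — true
for the near-diagonal high-identity pairs the screen admits (a full-width
fallback is used for short sequences and for `align_pair()` itself).

# Occupancy tiers, accumulation and openness

With $n$ genomes, a cluster present in all $n$ is **core**; in
$\ge \lceil 0.95\,n \rceil$ (but not all) **softcore**; in $\le 2$
**cloud**; otherwise **shell**. The ceiling form is the integer-safe
reading of "95–100%". For $n \le 20$, $\lceil 0.95 n\rceil = n$, so the
softcore tier collapses onto the core — which is why per-species tables
at $n = 8$ satisfy core + shell + cloud = pan exactly, while a 32-genome
table does not (softcore-but-not-core clusters sit between). Reports
print `N_softcore` as the threshold tier *including* core, so
`N_softcore + N_shell + N_cloud = N_pan` always holds.

`accumulation_curves()` adds genomes in `n_perm = 10` random orders
(matching the conventional ten randomizations) and records pan(N),
core(N) and the increment new(N). `fit_heaps()` regresses
$\log(\mathrm{median\ new}(N))$ on $\log N$ for $N = 2..n$: under the
decay law $\mathrm{new} = k N^{-\alpha}$ the slope is $-\alpha$, and
$\alpha < 1$ flags an open pan-genome. The decay-law reading (new genes
per added genome, not total pan size) is chosen because growth exponents
of ~0.2 together with "open when α < 1" only cohere under it; a
total-size power law with α ≈ 0.2 would be wildly superlinear. Zero
medians get a 0.5 pseudocount before logging so late flat stretches do
not drop points; the median (not the mean) across permutations feeds the
fit for robustness to ordering outliers.

Note that the simulator's i.i.d. finite-pool accessory design saturates:
once most of the 1200 accessory families have been seen, new-gene
increments fall off faster than $1/N$, so the fitted α on the default
reference simulation exceeds 1 (a *closed* flag). Real open pan-genomes
draw accessory genes from an effectively unbounded environmental pool,
which no fixed-pool simulation reproduces; the validated claims about
the fit are therefore the closed-form inversion of exact decay curves
and the stability of the flag across seeds, not the openness of any
particular dataset.

# ANI, species clustering and trees

`ani_matrix()` computes ANI as the mean percent identity over clusters
where both genomes contribute exactly one gene, measured on the
cluster's center-star alignment. This is an ortholog-averaged ANI
(orthoANI-flavoured) rather than the classic 1020-bp fragment-BLAST
estimator; it needs no external aligner and converges to the same
quantity on indel-free data. The 95% species convention applies
unchanged: `cluster_species()` single-links genomes with ANI ≥ 95%.

`center_star_align()` picks the longest member (ties by label) as the
center, aligns every other member to it, and merges on center
coordinates, packing insertions left within the maximal gap run observed
per position. For the star objective (sum of pairwise scores to the
center) the result is optimal, since each pairwise alignment is.

`jc_distance_matrix()` applies $d = -\tfrac34\ln(1 - \tfrac43 p)$ with
pairwise deletion of gap columns; saturated pairs ($p \ge 3/4$) are
capped at 5 substitutions/site and flagged rather than dropped, so
downstream tree builders always receive a finite matrix.

`build_nj()` wraps Saitou–Nei neighbor joining (the three-taxon case is
solved directly with the three-point formulas, which `ape::nj` does not
handle). Bootstrap supports, when requested, resample alignment columns,
rebuild the tree per replicate, and report the percentage of replicates
containing each internal bipartition. The per-gene trees default to no
bootstrap in the workflow scripts for runtime; the option mirrors the
conventional 100/1000-replicate settings. `build_upgma()` is
average-linkage clustering returned as an ultrametric tree; equal
distances are resolved by lexicographic taxon order so outputs are
stable. The reference tree for gene ranking is UPGMA on $100 -$ ANI,
i.e. the pan-genome ANI clustering itself.

The Jukes–Cantor model throughout (simulator, distances, expectations)
is a deliberate closure: the same model generates and measures, so
closed-form calibration checks are exact. Distances under a different
generating model would need only a swapped distance function.

# Tree comparison and representative genes

Splits are the nontrivial bipartitions of the unrooted tree.
`rf_distance()` is the symmetric difference of split sets.
`matching_split_distance()` solves the minimum-cost perfect matching
between split sets (pair cost = smaller leaf disagreement, unmatched
splits cost their smaller side) exactly with a hand-written $O(k^3)$
Hungarian algorithm — exact matching matters because the metric is
defined as the optimum, and split counts here are small (≤ leaves − 3).
`quartet_distance()` enumerates all $\binom{n}{4}$ quartets and compares
induced topologies via the four-point condition on unit-branch-length
path distances; unresolved quartets (from multifurcations) differ from
any resolved quartet and match each other. Sub-quadratic quartet
algorithms are out of scope at these sizes.

`select_representatives()` ranks each core gene tree by matching-split
and by quartet distance to the reference, sums the two ranks (average
ranks on ties), and selects the top 5% by rank sum. The rank-sum
combination is this package's choice — simple and scale-free — since no
canonical way of combining the two metrics exists; single-metric ranking
is available via `metric =`. Ties at the selection boundary are
included, so the selected set can exceed the nominal fraction; published
counts in comparable analyses (e.g. 40 selected from 940 where 5% is 47)
show that eligibility filtering and tie policy move this number, so no
exact count is asserted — only the direction that longer genes, carrying
more sites and hence lower tree-estimation noise, are preferentially
selected.

The length-preference experiment needs a *resolvable* true topology:
the pan-genome simulator's two-level species tree is a star within each
clade, so within-clade disagreement is pure noise for every gene and no
length advantage can exist there. The experiment therefore evolves 10
long (1300 bp) and 190 short (200 bp) genes with `simulate_alignment()`
along a structured 30-taxon coalescent tree of root-to-tip depth 0.1
substitutions/site, ranks their NJ trees against the UPGMA tree of the
pooled identity matrix, and pools three replicate simulations before
comparing median selected vs unselected lengths — the per-replicate
outcome is a 10-gene median and would otherwise hinge on a single tree
draw. The 200-bp short class is deliberately noisier than real short
core genes to make the designed contrast unambiguous; only the
direction of the effect is asserted.

# Consensus SNPs

`build_consensus()` takes per column the unique plurality base; columns
with a plurality tie, a gap, or a non-ACGT character are ambiguous and
excluded (no IUPAC coding — it would make counts ill-defined). A **SNP**
is an unambiguous column where at least one sequence deviates from the
consensus; the polymorphic-column count is the primary total, chosen as
the most parsimonious reading of consensus-based SNP identification, and
per-genome deviation counts are reported alongside for transparency.

# The HGT screen

`detect_hgt()` is explicitly a *simplified* best-match +
tree-incongruence screen, not a re-implementation of a full HGT
pipeline. For each single-copy gene copy: compute the mean identity to
same-species copies and the best identity to each foreign species; flag
when (1) the best foreign identity exceeds the within-species mean by
more than `min_gap = 2` percentage points and (2) the smallest clade
enclosing the copy in the cluster's gene tree is dominated by that
foreign species. The margin exists because a planted transfer creates a
*mirror* signal on the donor side: the recipient's derived copy is the
donor's best foreign match and sits next to it in the gene tree, so with
a bare `> 0` threshold the donor copy is systematically flagged too.
Within-species identity spread in the calibrated design is a fraction of
a percentage point while a genuine transfer shifts the recipient's gap
by ≈ +3–6 points, so a 2-point margin separates the two regimes with
room on both sides. Detection has a hard limit by construction: a
transfer subsequently overwritten by divergence at between-species scale
is indistinguishable from vertical descent and is (correctly) not
flagged.

# Enrichment

`tabulate_fold_extension()` counts annotated clusters per category in
the pan-genome, the softcore tier and the core, and reports pan/subset
ratios (1-decimal display, full precision kept internally — rounding
never feeds back into computation). `enrich()` is an upper-tail
hypergeometric test per category with Benjamini–Hochberg adjustment,
rich factor = set count / background count. The background defaults to
all annotated clusters of the pan-genome, matching the setting where
species-specific sets are compared against the full catalog; both the
statistic and the background convention are stated assumptions, since
enrichment conventions vary, and both are configurable by passing a
different background.

# Problem sizes and numerical choices

The reference simulation used by the workflow scripts, the end-to-end
test and `scripts/acceptance.R` is 4 species × 8 genomes, 600 core +
1200 accessory families of 900 bp, 5 planted transfers — about 26,000
genes, chosen so the complete pipeline runs in a few minutes on one
core while keeping per-pair site counts (≈ 540,000 core sites per genome
pair) large enough that Jukes–Cantor calibration checks at 3 standard
errors are tight. Supporting simulations in the tests are smaller (tens
of families, 150–600 bp) and state their sizes inline. Other numerical
conventions collected in one place: alignment traceback ties prefer
diagonal, then gap-in-second; clustering scores are +1/−1/−2 while
center-star alignment uses a stiffer −4 gap (under −2, a compensating
gap pair can spuriously beat the diagonal on long substitution-only
homologs, padding "ungapped" family alignments with gap columns); cluster
ids are assigned by smallest member key; saturated distances cap at 5;
UPGMA/hclust ties follow lexicographic label order; Heaps' pseudocount is
0.5; the species threshold is 95% ANI; the HGT margin is 2 percentage
points.

# Known limitations

* No indels, recombination within genes, rate heterogeneity or
  amino-acid sequences in the simulator; the positional k-mer prefilter
  inherits the no-indel assumption.
* ANI is ortholog-averaged, not fragment-based; absolute values can
  differ slightly from BLAST-fragment ANI on real genomes even though
  the 95% convention transfers.
* The HGT screen detects recent, single-gene, cross-clade transfers
  only; ancient or within-clade transfers and transfers into the
  accessory genome are outside its design.
* Maximum-likelihood tree inference and model selection are out of
  scope; all trees are distance-based (NJ/UPGMA) under Jukes–Cantor.
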