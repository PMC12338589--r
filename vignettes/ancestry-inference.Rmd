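---
title: "Inferring prokaryotic ancestry of eukaryotic protein families with epocr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring prokaryotic ancestry of eukaryotic protein families with epocr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Core eukaryotic genes that trace back to the last eukaryotic common
ancestor (LECA) descend from a mixture of archaeal and bacterial donors.
For a single protein family, the donor shows up in a gene tree as the
prokaryotic clade that branches as sister to the eukaryotic clade. Reading
this sister relationship directly off an estimated topology is brittle:
trees of deep divergences have weakly supported backbones, and a single
arbitrary rearrangement flips the apparent ancestor. `epocr` instead treats
each plausible sister as an explicit hypothesis, builds the corresponding
constrained topology, and asks how well each constraint explains the
alignment. The unit of analysis is an EPOC — a eukaryotic–prokaryotic
orthologous cluster: one eukaryotic protein family, its prokaryotic
homologs, their alignment, and their gene tree.

## The procedure

For each EPOC the pipeline runs these stages, each exposed as an exported
function and orchestrated by `run_pipeline()`:

1. **Taxonomy-aware subsampling** (`taxonomy_aware_subsample()`). Large
   families are reduced to at most 30 eukaryotic and 70 prokaryotic
   sequences. Closest leaf pairs are pruned only when they form a
   label-monophyletic cherry, keeping the leaf closest to the root and
   accounting pruned leaves to the survivor, so rare taxa survive and the
   result approximates a maximum-diversity representation. If the greedy
   pass converges above the target, leaves with the fewest pruned
   relatives — isolated singletons first — are deleted until the cap.
2. **Information trimming** (`trim_alignment()`). Columns must carry more
   than 0.15 bits of information, defined as log2(20) minus the Shannon
   entropy of the column's amino-acid distribution over non-gap residues
   (0.2 bits is the profile-construction setting). No pseudocounts: the
   formula is applied to raw frequencies, `0*log(0) = 0`, and non-standard
   residue codes count as gaps because they carry no usable frequency.
3. **Long-branch pruning** (`prune_branch_outliers()`). A log-normal is
   fitted by maximum likelihood to all positive branch lengths; every
   subtree whose stem exceeds the 99.5% quantile is removed, catching long
   terminal branches and diverged clades in one rule. Trees losing their
   whole eukaryotic clade or more than 30% of leaves are discarded. The
   lower tail is not pruned: branch lengths are bounded below by zero, so
   a one-sided upper cutoff is the whole interval. Zero-length branches
   are excluded from the fit but never pruned, and a degenerate fit
   (log-sd below 1e-8, e.g. all branches equal) disables pruning rather
   than producing arbitrary cutoffs.
4. **Weighted midpoint rooting** (`weighted_midpoint_root()`). The root is
   placed on the edge and position that equalize the total branch length
   on the two sides; within an edge the balance point is a linear solve,
   clamped to the edge. This is a data-structure root that makes "toward
   the root" well defined; it is not a phylogenetic rooting claim. Ties
   between edges are broken by preorder edge index so results are
   reproducible.
5. **Soft-LCA clade detection** (`detect_clades()`). Requiring strict
   monophyly per taxon label fails on real trees, where single leaves are
   often locally misplaced. Every ancestor of each monophyletic group of a
   label is scored with `(n/clade_size) * (n/total_label)` — purity times
   scope — and candidates are accepted greedily by score, skipping
   overlaps. Validity is a size/purity rule only (at least 3 prokaryotic
   or 5 eukaryotic sequences at purity strictly above 0.8); the score
   itself is metadata, never a filter, because it depends on the label's
   total count and is incomparable across EPOCs. Prokaryotic clades are
   detected per class label; the eukaryotic clade is detected at domain
   level, since a LECA-tracing clade by construction spans many eukaryotic
   class labels. Zero eukaryotic or zero prokaryotic clades reject the
   EPOC, and more than three eukaryotic clades signal irreducible
   paraphyly and likewise reject it.
6. **Constrained-topology ELW scoring** (`score_sisters()`). The 12
   prokaryotic clades closest to the eukaryotic clade root by topological
   distance (internal nodes strictly between the two nodes, root excluded;
   ties broken by larger clade, then label) are enumerated as sister
   hypotheses. For each, the eukaryotic subtree is pruned and regrafted
   onto the midpoint of the candidate's stem, enforcing three groups:
   eukaryotes, the candidate, everything else. Per-site log-likelihoods
   are computed by Felsenstein pruning under a fixed amino-acid model, and
   hypotheses are scored by Expected Likelihood Weights: resample site
   indices with replacement (RELL, 1000 replicates), convert each
   replicate's total log-likelihoods to normalized likelihood weights, and
   average. ELW lies in [0,1] and sums to one over candidates, so it reads
   as model-selection confidence for "this clade is the sister".
7. **Core-set filtering and aggregation** (`core_filter()`, `aelw()`).
   Only sisters with 0.4 < ELW < 0.99 are treated as reliable: below 0.4
   the data cannot discriminate candidates; at or above 0.99 the candidate
   is typically a eukaryote-like sequence branching inside the eukaryotic
   clade, i.e. post-LECA horizontal transfer, except that ELW exactly 1 is
   admitted for EPOCs annotated with configured categories (default the
   oxidative-phosphorylation pathway, where genuine near-certain
   mitochondrial ancestry is expected). EPOCs must be annotated and their
   eukaryotic clades must span more than 5 distinct labels including both
   Amorphea and Diaphoretickes — the LECA scope check. Average ELW (aELW)
   per functional category and candidate taxon summarizes ancestry across
   families; categories with fewer than 20 EPOCs are flagged.
8. **Stem-length statistics** (`stem_lengths()`,
   `stem_distribution_analysis()`). The stem length SL is the path from
   the node joining eukaryotes with their inferred sister (FECA) to the
   eukaryotic clade root (LECA); the normalized stem length is
   NSL = SL / median LECA-to-leaf path over eukaryotic leaves. We read
   "median eukaryotic branch length" as the median root-to-leaf path from
   the LECA rather than the median of individual edges: per-edge medians
   depend on tree shape and resolution, while leaf paths measure the
   quantity the normalization needs, post-LECA divergence per site. Groups
   of EPOCs sharing an ancestor taxon are compared by kernel density
   (Scott's bandwidth), percentile summaries, bootstrap CDF bands on a
   common grid (200 replicates, grid spanning [0, pooled 99th percentile]
   in 200 points), per-grid two-sample comparisons, and Mann–Whitney tests
   of the raw NSL values below and above the 0.3 and 0.35 split points.

## Per-grid CDF comparison: why two p-value columns

Plotting a Mann–Whitney p-value between two groups' bootstrap CDF-value
distributions at each grid point is how such bands are usually annotated,
and `stem_distribution_analysis()` reports that column (`p_mw`). It is not,
however, a calibrated test: bootstrap replicates concentrate around each
group's empirical CDF, so the test detects the sampling noise of the
empirical CDFs themselves; under identical generating distributions at
n = 1000 per group, most grid points come out "significant". The
procedure's p-value (`p_boot`) is therefore a paired bootstrap test of the
CDF difference — the fraction of replicates with the difference on either
side of zero, doubled — which is approximately uniform under the null
(measured at or below ~2.5% of grid points under 0.05 across seeds) while
retaining power against real shifts. Both columns are returned so plots
can be annotated either way, but calibration claims rest on `p_boot`.

## The substitution models

Two time-reversible models are built in. `eq20` is the 20-state equal-rates
model (uniform exchangeabilities and frequencies); its transition
probabilities have the closed form
`P(same) = 1/20 + (19/20) exp(-20 t / 19)`, which gives the test suite
analytic oracles for the likelihood machinery and the sequence simulator.
`lg` uses the empirical LG exchangeabilities and frequencies for realism.
Both are scaled to unit expected rate so branch lengths are substitutions
per site. The reference analysis selected LG/Q.pfam with rate categories by
model testing in an external ML package; model selection is out of scope
here and a fixed model is a configuration choice. Likelihood evaluation is
standard Felsenstein pruning with per-node column scaling; the
implementation agrees with `phangorn::pml` to 1e-6 on test fixtures and is
exercised against two-leaf closed forms and the pulley principle.

Branch lengths on constrained topologies are refreshed by bounded
univariate (Brent) likelihood maximization, tolerance 1e-4, cycling twice
over the edges the regraft touched: the eukaryotic stem, the two halves of
the split sister stem, and the healed edge at the former attachment. Edges
elsewhere in the tree are unaffected by the regraft and keep their master
estimates; an `"all"` mode optimizes every edge for cross-checks. This is
the desk-scale analogue of a constrained ML search — the topology is fixed,
only lengths move.

## The synthetic-data generator

`simulate_epoc()` emulates the object the pipeline consumes: a gene tree
with one monophyletic eukaryotic clade (default 10 leaves, cycled over
eight class labels spanning both Amorphea and Diaphoretickes so the LECA
scope check is satisfiable), attached by a stem of known length (default
0.3 substitutions/site) as sister to a known prokaryotic clade among
labelled others (default three clades of eight), and an alignment evolved
along the tree (default 300 sites, `eq20`). Within-clade topologies are
pure-birth; clades are scaled to a root-to-tip depth of 0.3 and hang off a
0.5-deep backbone. Optional noise plants long-branch outliers (terminal
branches multiplied by a known factor) and horizontal-transfer-like leaves
(a prokaryotic leaf relabelled off-clade). All draws flow from per-stage
generators derived from one seed (`stage_seed()`), so the pre-inflation
tree of a noisy run is bit-identical to the clean run's tree and truth
records stay exact.

Defaults were chosen once to represent the study conditions: stems of 0.3
with clade depths of 0.3 put the planted signal at the scale where
constrained hypotheses are distinguishable but not trivial at 300 sites,
and 25–40 leaf trees match the subsampled size regime the pipeline
operates in. The stem-cohort generator's default NSL base distribution,
log-normal(-1.39, 0.5), places about 70% of stems below 0.3, matching the
reported quantile structure of real stem-length sets; the planted
alternative shifts the log-location by +0.5. A literal additive shift of
strictly positive NSL values would empty the below-split stratum entirely,
so "shifted" cohorts are shifted on the log scale.

What the generator does not emulate: indels (alignments are gap-free
unless trimmed), among-site rate variation, alignment error, model
misspecification (sequences evolve under the scoring model), and
tree-estimation error (the pipeline consumes the true simulated tree, as
tree inference is external to the package). Passing recovery tests
therefore demonstrates the correctness and statistical behaviour of the
pipeline logic, not robustness to upstream estimation noise in real data.

## Numerical and design choices

- **Soft-core filtering** counts coverage by distinct species identifiers
  for both domains by default; the alternative reading of eukaryotic
  coverage as a sequence fraction is available via `euk_mode =
  "sequences"`. The species-fraction default keeps the two domains on the
  same semantics.
- **Supergroup membership** is a declared taxonomy column; unknown values
  collapse to "other". The package never resolves external taxonomies.
- **Outlier fit** uses all branch lengths (terminal and internal). Fitting
  only terminal stems is a supported reading, but internal branches are
  exactly what distinguishes a diverged clade from a run of long leaves,
  and the removal rule targets both.
- **Supercluster partitioning** embeds the patristic distance matrix in
  two dimensions by classical multidimensional scaling and groups the
  embedding by single-linkage agglomeration, cutting only where the
  smallest removed merge exceeds five times the largest kept merge and
  taking the coarsest such cut. Single-cluster output is the default for
  homogeneous trees. The hyperparameters are exposed; the contract is
  planted-partition recovery, and the tests plant two and three clades at
  50-fold separation.
- **Tie-breaks** are deterministic everywhere: preorder edge index for
  rooting, (distance, -size, label) for hypothesis order, name order for
  equal-depth leaves in subsampling.
- **Seeding**: every stochastic step takes a seed derived from the global
  seed and a stage name, so independent stages can be reordered without
  changing each other's draws, and identical configurations reproduce
  artifacts bit-identically.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data:
50 EPOCs of 25–40 leaves and 300 sites for sister recovery (1000 RELL
replicates), 200 contaminated 26-leaf trees for pruning, 100 planted trees
for clade detection, cohorts of 500–1000 records with 200 bootstrap
replicates for the stem statistics. These sizes keep a full run in minutes
on one core while leaving the statistical conclusions stable across seeds.

## Limitations

ELW here is computed by RELL over fixed per-site log-likelihoods with
fixed-topology branch refreshing, not by full per-replicate re-estimation;
with externally re-optimized constrained trees the weights would differ in
the third decimal but not in ranking on the fixtures tested. The
eukaryotic clade is detected at domain level, so two eukaryotic families
fused in one tree resolve as paraphyly rather than as separate families.
The 70%-of-stems-below-0.3 quantile is a property of a dataset, not an
assertion of the package; it is reported by the analysis scripts, not
asserted by tests. Real-data caveats — contamination, alignment error,
incomplete taxon sampling — are upstream of this package's inputs.
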