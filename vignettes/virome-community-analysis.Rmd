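---
title: "Methods: community ecology and compositional analysis of viromes"
author: "viromeEco"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community ecology and compositional analysis of viromes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viromeEco)
```

# Scope and data model

`viromeEco` analyzes viromes summarized as a sample-by-viral-family matrix of
read counts, the typical end product of read-based taxonomic classification of
metatranscriptomes. The central container is the `ViromeExperiment` S4 class
(a `SummarizedExperiment` with families as rows and samples as columns), which
couples the integer count matrix with two annotation layers:

* per family, the **host domain** (`eukaryote`, `prokaryote_archaea`, or
  `uncertain`, the last being the reserved `UNCERTAIN_FAMILY` bucket that
  receives reads classified to viruses without a family-level rank);
* per sample, the host **species**, **phylum**, and **habitat** (a closed
  five-category vocabulary: brackish, freshwater, intertidal zone, marine,
  terrestrial).

All diversity and compositional analyses operate on the eukaryote-virus
submatrix obtained from `partitionByHostDomain()`; phages and the uncertain
bucket only enter the per-sample host-domain fractions.

# Sample selection from run metadata

`filterEligible()` applies three eligibility criteria to SRA-style run
records: library strategy `RNA-Seq`, average read length **at least** 75
bases, and **strictly more than** 3 Gbases sequenced. The read-length bound is
inclusive and the base-count bound strict, reflecting the different phrasings
of the two rules ("greater or equal" vs "greater than"); the boundary record
(RNA-Seq, 75 b, 3 Gb + 1 b) is retained.

`sampleSelection()` then draws at most one run per harmonized species
(`harmonizeSpeciesName()` reduces names to binomials, or `Genus sp.` where
species identity is uncertain) and at most 20 species per phylum (per-phylum
overrides supported, e.g. 39 for an unusually species-rich phylum). Runs
below 30 Gbases are exhausted before any larger run is considered — both when
choosing which species fill a phylum and when choosing the run within a
species. The 30 Gb priority is a compute-saving device, not a statistical
one; since no weighting scheme is specified for the random draw, species and
runs are sampled uniformly. Habitat labels come from a user-supplied ecology
table (`assignHabitat()`); any label outside the five-category set is a
validation error rather than a new category.

# Diversity analysis

Per sample, richness is the number of families with positive counts and
Shannon diversity is $H' = -\sum_j p_j \ln p_j$ over the within-sample family
proportions. The logarithm base is not dictated by the formula's usual
presentation; natural log is the package default (and the only base used in
the pipeline), configurable in `shannonIndex()`.

Group comparisons use ordinary ANOVA with AIC model selection
(`fitAnovaSelect()`): candidates are each single factor and the additive
combination, fitted after dropping factor levels with fewer than 5
observations. The AIC convention is fixed as $n\ln(\mathrm{RSS}/n) + 2k$ with
$k$ = number of coefficients + 1; only differences between candidates matter,
so the omitted Gaussian constant is irrelevant. Homoscedasticity is checked
with Levene's test via `car::leveneTest` (median-centered Brown–Forsythe by
default, mean-centering by flag). When Shannon diversity is heteroscedastic
across phyla, the pipeline applies a Box–Cox family transform with
$\lambda = 2.5$ before fitting. The upstream description of this step reads
"the inverse of the Box-Cox transformation"; both directions are implemented
in `boxcoxTransform()` and the pipeline default follows that wording
literally (the inverse map $z \mapsto (\lambda z + 1)^{1/\lambda}$ applied to
raw $H'$, which is monotone increasing and therefore preserves all orderings).
The ambiguity is deliberate and surfaced here rather than silently resolved.

Post hoc contrasts use Tukey HSD (`TukeyHSD`, Tukey–Kramer under imbalance)
with a compact letter display computed by the insert-and-absorb algorithm
(`tukeyHsdLetters()`): groups share a letter exactly when their difference is
not rejected; ties in letter assignment are resolved by factor-level order so
displays are deterministic.

Family accumulation curves (`accumulationCurve()`) subsample $s$ samples
without replacement, 50 times per size by default, record the pooled richness
of the union, and summarize with an OLS fit of mean richness on $\ln s$. Only
groups with at least 15 samples are admitted by default, matching the
multivariate subset rule.

# Compositional analysis

Counts are compositions: only relative information is meaningful. The
preparation order is fixed and matters:

1. `toRelativeAbundance()` — row-normalize eukaryotic counts;
2. `filterFamilies()` — drop families whose mean relative abundance is below
   0.01% and renormalize. The boundary is **inclusive** (a family at exactly
   1e-4 stays): the two upstream phrasings ("did not reach", "higher than")
   conflict at the boundary, and "reach" was read as attainment. Rows are
   renormalized after the filter because the subsequent zero-replacement
   formula assumes unit-sum rows;
3. `czmReplaceZeros()` — count-zero multiplicative replacement: in sample $i$
   with depth $n_i$, zeros become $\delta_i = 0.65/(n_i+1)$ and nonzero parts
   shrink by $1 - z_i\delta_i$. This keeps rows on the simplex and preserves
   nonzero-part ratios exactly (to 1e-12 in the tests). The 0.65 label and
   the $1/(n_i+1)$ detection limit follow the count-zero convention of the
   multiplicative-replacement literature, since no parameters are given
   upstream;
4. `clrTransform()` — centered log-ratio coordinates, rows summing to zero
   (1e-10 tolerance in tests).

Euclidean distances on clr rows are Aitchison distances
(`aitchisonDistances()`); they are invariant to per-sample count scaling and
to perturbation by a common composition. `centroidDistances()` takes the
phylum centroid as the arithmetic mean of the group's clr rows (a
PCoA-median alternative was considered and rejected: "centroid" conventionally
denotes the mean, and the mean is what the PERMANOVA decomposition uses). `aggregateByGroup()` averages sample
compositions with equal weight per sample *before* the clr transform and
clusters profiles with Ward.D2 on Euclidean distances.

# PERMANOVA, PERMDISP and pseudo-AIC

`permanova()` partitions the Gower-centered matrix
$G = (I - \tfrac{1}{n}\mathbf{1}\mathbf{1}')(-\tfrac{1}{2}D^2)(I -
\tfrac{1}{n}\mathbf{1}\mathbf{1}')$: the SS explained by a design projection
$H$ is $\mathrm{tr}(HG)$, terms are sequential (Type I) in formula order,
and pseudo-$F$ follows the standard distance-based ANOVA form. Monte-Carlo
p-values use the $(1+b)/(1+m)$ convention (never zero); `exhaustive = TRUE`
enumerates all $n!$ label permutations for $n \le 8$ and returns the exact
tail fraction with the identity included. On the 4-point toy configuration
$A=\{0,1\}$, $B=\{3,4\}$ this gives $SS_{total}=10$, pseudo-$F = 18$ and
exact $p = 2/6$, and on random data the decomposition agrees with
`vegan::adonis2` to 1e-8 (vegan is used only as a cross-check oracle in the
tests, never as the implementation).

`permdisp()` embeds the distance matrix by principal coordinates, keeping
negative-eigenvalue axes as imaginary coordinates: a sample's squared
distance to its group center is the real part minus the imaginary part,
truncated at zero. For Euclidean-embeddable input this reproduces direct
coordinate-space distances to 1e-8. The center is the centroid by default
("centroid" is the stated choice); a Weiszfeld spatial median is available
for parity with the reference implementation's default. The F statistic on
the distances is tested by permuting group labels of the distance values.

Model comparison across PERMANOVA fits uses a **pseudo-AIC**,
$n\ln(SS_{res}/n) + 2k$ with $k$ = model df + 1. This is the package's own
definition: neither the distance-based ANOVA literature nor its reference
implementations define an AIC, and how one was obtained upstream is unstated.
It is a relative ranking device for models on the same distance matrix, not a
likelihood quantity, and is flagged as such in the documentation.

# The bootstrap equivalence network

Unbalanced group sizes distort PERMANOVA, so pairwise phylum comparisons run
on balanced bootstrap resamples (`runBootstrap()`; defaults: group size 15,
1500 iterations, $\alpha = 0.05$, support threshold 0.2). Each iteration:

1. draws 15 observations per phylum with replacement;
2. picks one drawn observation at random and imputes a new phylum for it
   (uniform over the other phyla — the distribution is unspecified upstream),
   relabeling all its bootstrap duplicates;
3. trims the imputed phylum back to 15 by dropping its own members, keeping
   the shuffled observation;
4. refills the donor phylum, never re-drawing the shuffled observation;
5. recomputes relative abundance → 0.01% filter → CZM → clr on the resampled
   count matrix (the upstream step list names only the clr transform; running
   the full preparation per iteration is a documented package decision, since
   the filter's family set is resample-dependent);
6. runs one-way PERMANOVA and PERMDISP for each of the $n(n-1)/2$ phylum
   pairs, adjusts all $2 \cdot n(n-1)/2$ p-values of the iteration as a single
   Benjamini–Hochberg family ("total number of tests per iteration" read
   literally; a per-test-type alternative is available by flag), and codes
   each pair as `LOC_DIFF` (PERMANOVA rejected, PERMDISP accepted),
   `BOTH_REJECT`, `DISP_ONLY`, or `NEITHER`.

A pair's **support** is the fraction of iterations with any code other than
`LOC_DIFF` — the procedure calls a difference significant only when the
location test rejects while the dispersion test does not — and an edge
connects two phyla when support strictly exceeds 0.2.

Two properties of this procedure are worth knowing before interpreting a
network. First, bootstrap duplication makes the within-iteration permutation
tests anticonservative for the hypothesis "the two phylum pools were drawn
from one distribution"; support for identically distributed phyla is
therefore high but not $1-\alpha$. Second, the imputation step plants one
foreign observation into a random phylum each iteration; for strongly
separated phyla that observation drags the recipient group's centroid and
makes PERMDISP reject, turning `LOC_DIFF` into `BOTH_REJECT` for pairs
involving that phylum. With $n$ phyla this affects a given pair in roughly
$2/(n-1)$ of iterations — about 13% at $n = 16$, comfortably below the 0.2
support threshold, but **the threshold is only meaningful at network size**:
with very few phyla the artifact dominates and separated pairs would appear
connected. The package's recovery tests therefore run at $n = 16$ (fourteen
divergent phyla plus one phylum split into two identically generated
pseudo-phyla) and check that the split pair is recovered with support > 0.8
while the most separated divergent pair stays below 0.2.

# Bipartite network structure

`buildBipartite()` forms the quantitative host × family interaction matrix
from relative abundances (equal-weight group aggregation or
presence-fraction weights optional, including the "present in ≥ 20% of the
samples of at least one phylum" display filter). Indices:

* **Linkage density** (`linkageDensity()`): half the sum over both sides of
  the marginal-weighted effective partner counts, where a node's effective
  partners is $e^{H}$ of its interaction weights.
* **H2′** (`h2Prime()`): interaction entropy standardized between the
  extremes attainable under the observed marginals — maximum at the
  independence (outer-product) table, minimum from a greedy marginal-packing
  heuristic (the exact minimum is a transportation problem; the greedy value
  is checked against closed forms on small matrices). Clipped to [0, 1].
* **NODF** (`nodf()`): mean paired-overlap percentage over all row and column
  pairs, a pair contributing zero unless the fuller node strictly exceeds the
  poorer one. Binarization is weight > 0 exactly. The `NODF2` variant sorts
  by fill first; because the decreasing-fill condition is evaluated on fills,
  sorted and unsorted values coincide, and both match a brute-force oracle on
  random matrices.
* **Barber Q** (`qModularity()`): bipartite modularity
  $\frac{1}{F}\sum_{ij}(A_{ij} - k_i d_j/F)\,\delta(g_i, g_j)$, maximized by
  label propagation with random restarts and a local-move refinement. The
  one-module baseline ($Q = 0$) is always admissible, so the result is never
  negative; runs are deterministic under a seed. Two disconnected equal-weight
  blocks give exactly $Q = 0.5$.
* **d′** (`dPrime()`): per-node Kullback–Leibler divergence from partner
  availability, standardized by the greedy-packing maximum (allocate the
  node's total to the scarcest partners first, capped by their marginals);
  0 = availability-matched generalist, 1 = maximal specialist.

Null models use Patefield's r2d algorithm via `stats::r2dtable`, which
preserves row and column totals exactly. Non-integer weight matrices are
scaled by $10^4$, rounded, sampled, and rescaled (the algorithm is defined
for integer tables). `nullZtest()` compares an observed index with the null
ensemble (1000 draws by default) and warns when the observed value or null
mean sits within 2 null SD of a closed range boundary, where the normal
approximation breaks down. On dense synthetic matrices the binarized nulls
can be completely filled, making NODF constant across the ensemble; the
z-test then refuses the zero null SD and the pipeline reports `NA` for that
index.

# The synthetic-data generator

`simulateVirome()` emulates grouped compositional count data, not
sequencing: a shared base composition is drawn from a symmetric Dirichlet
(concentration 5 over 40 families by default — uneven but not degenerate
family abundances); each phylum perturbs the log-composition with iid normal
noise of sd `phylumEffect` (a logistic-normal divergence dial; 0 means all
phyla share one composition and samples are exchangeable, which underpins the
type-I-error tests); habitats add a log-ratio shift of magnitude
`habitatEffect` on a fixed random quarter of the families; each sample
independently loses families with probability `zeroInflation` (0.2 —
structural absence, the dominant source of within-phylum dispersion);
sequencing depth is log-normal (meanlog 10, sdlog 0.5 in natural log —
median about 22,000 classified eukaryote-virus reads, a right-skewed depth
distribution of the kind seen in real surveys); counts are multinomial, so
row totals equal the drawn depths exactly. One master seed drives everything
through the documented splitting scheme `deriveSeed()`.

What the generator does **not** emulate: classifier error and reference-database
bias (misclassified conserved host genes inflating particular families),
phylogenetic correlation between species within a phylum, habitat–phylum
confounding, and library-preparation effects. Passing recovery tests on this
generator therefore shows the statistical machinery is correct and calibrated
under its stated model, not that the biological conclusions of any particular
survey are robust to those unmodeled features. No distributional model of the
real data is specified upstream; every generator choice is a stand-in and is
parameterized so users can move it.

# Problem sizes and numerical choices

The test and acceptance runs use desk-scale sizes chosen as the smallest that
make the statistical claims meaningful: 4 phyla × 15 samples (the balanced
group size of the bootstrap) for calibration and recovery, 500 replicates for
the type-I envelope, 100 for power/recovery rates, 200 bootstrap iterations
at 99 permutations per within-iteration test for the equivalence network at
$n = 16$ phyla, and 1000 Patefield draws for the 2×2 null law. Permutation
counts of 999 (global fits) and 199 (per bootstrap test) are the package
defaults; the latter is the main runtime knob of `runBootstrap()`.

Other fixed numerical choices: Monte-Carlo p-values use $(1+b)/(1+m)$;
exhaustive enumeration is limited to $n \le 8$; eigenvalues within
$10^{-8}\,\max|\lambda|$ of zero are dropped in the PCoA embedding; Ward2
merges are deterministic (ties resolved by `hclust`'s ordering); the
compact-letter-display insert-and-absorb resolves ties by group order;
degenerate inputs (all-zero samples, single-level factors, singleton groups,
saturated models, zero residual SS, zero null SD) raise informative errors
rather than silent answers.

# Known limitations

* The pseudo-AIC for distance-based models is a heuristic ranking score.
* The H2′ minimum and d′ maximum use greedy packing heuristics; exact optima
  would require solving transportation problems per node.
* The modularity optimizer is stochastic; restarts mitigate but do not
  eliminate local optima (the seed makes results reproducible).
* The bootstrap equivalence network inherits the anticonservativity of
  permutation tests on bootstrap-duplicated data and the imputation artifact
  discussed above; supports are comparative evidence, not calibrated
  probabilities.
* Species within a phylum are treated as independent observations;
  phylogenetic dependence is out of scope.
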