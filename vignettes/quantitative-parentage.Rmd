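---
title: "Quantitative genotypes for parentage assignment and pooled-sample analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genotypes for parentage assignment and pooled-sample analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantpar)
```

## The problem

Low-density SNP panels (a few dozen markers) are cheap enough to genotype
every animal in an aquaculture breeding program, but their raw output is
noisy: per-SNP genotype clusters have heterogeneous positions and spreads,
platform software fails to call a substantial fraction of assays, and a hard
genotype call throws away information exactly where the data are most
ambiguous. `quantpar` keeps genotypes *quantitative* throughout. Each assay
is reduced to an allelic proportion and each genotype is represented as a
2×2 probability matrix over ordered allele pairs; parentage likelihoods,
pedigree reconstruction, pooled allele-frequency estimation and
family-contribution deconvolution all consume these matrices directly. The
same machinery also scores the two classical alternatives — a discrete call
perturbed by an assumed error rate, and mismatch-counting exclusion — so the
three error models can be compared on one dataset.

## From raw areas to genotype matrices

A two-channel assay reports areas $a_1, a_2$ and uncertainties $u_1, u_2$
for the A and B alleles. After clamping each uncertainty-adjusted channel at
zero, the allelic proportion is the polar angle rescaled to $[0,1]$:

$$p = \frac{\tan^{-1}\!\big((a_2-u_2)/(a_1-u_1)\big)}{\pi/2}.$$

Assays with adjusted intensity $(a_1-u_1)+(a_2-u_2)$ below 3.0 platform
units are treated as failed reactions (strictly below for individual
samples; at-or-below for pools, whose failure rule is conventionally
inclusive). The clamp is our own convention for sub-uncertainty signals —
the transform is otherwise undefined for negative channels — and combined
with `atan2` it guarantees $p \in [0,1]$.

Per SNP, samples with a platform call provide calibration: class means
$\mu_{AA}, \mu_{AB}, \mu_{BB}$ and standard deviations
$\sigma_{AA}, \sigma_{AB}, \sigma_{BB}$ of $p$, estimated per genotype
class without rescaling the proportions (cluster means are generally *not*
at 0, 0.5, 1, and the heterozygote mean can sit well off-centre). A SNP
needs at least `min_class_n = 3` called samples in every class and strictly
increasing class means to be usable; class standard deviations are floored
at $10^{-3}$ so a cluster of identical values cannot produce a degenerate
density spike. The Welch statistics $\tau_A$ (between the AA and AB
clusters) and $\tau_B$ (AB to BB) summarise how well each interval of the
$p$ axis separates genotypes; they later weight pooled-frequency estimates.

The quantitative genotype matrix evaluates the three class densities at the
sample's $p$, giving the two ordered heterozygote cells half the
heterozygote density each, and normalises:

$$G \propto \begin{pmatrix}\phi_{AA} & \tfrac12\phi_{AB}\\
\tfrac12\phi_{AB} & \phi_{BB}\end{pmatrix}.$$

Densities are computed in log space with max-subtraction before
exponentiation, so a $p$ far outside all clusters still yields a valid
matrix; only if every log-density is non-finite is the genotype missing.
Three further matrix flavours derive from $G$: the discrete matrix $D$
(unit mass on the best unordered genotype when its probability exceeds
0.98, i.e. 0.49 per ordered heterozygote cell), the perturbed matrix
$M = (1-\varepsilon)D + \varepsilon FF'$ with $F$ the allele-frequency
vector, and the missing-parent matrix $FF'$ itself. Two error rates are
available per SNP: the estimated rate $\hat\varepsilon$ (mean residual
uncertainty of the quantitative genotypes, $1 - $ mean best-genotype
probability) and the assumed rate
$\tilde\varepsilon = \max(\hat\varepsilon, 0.01)$, which concedes a 1%
error floor to even the cleanest assay.

## Trio likelihoods and LOD scores

A parent's transmission vector is $T = (G\mathbf{1} + G'\mathbf{1})/2$; the
general row-plus-column form is kept so phase-known (asymmetric) matrices
would remain valid input. For a candidate sire and dam, the expected
offspring genotype distribution is $T_s T_d'$, and the marker likelihood is
the Hadamard sum

$$L = \mathrm{sum}\big((T_s T_d') \circ G_o\big),$$

with the null likelihood $L_0$ replacing both parents by $FF'$ (allele
frequencies are estimated from the candidate-parent generation as mean
matrix-implied dosages). The LOD of a trio is
$\sum_j \ln(L_j/L_{0j})$ over SNPs at which the offspring and every named
parent have a genotype; natural logarithms are used (the likelihood
literature's convention — the base only rescales all scores). One convention
worth noting: with the heterozygote mass split 0.5/0.5 across the two
ordered cells, raw marker likelihoods for certain heterozygotes are half
the unordered Mendelian probability; the halving cancels in every
likelihood ratio, so LOD scores are representation-invariant.

A score is retained only when at least `min_snps = 10` markers are jointly
informative. A marker with zero trio likelihood contributes $-\infty$:
the trio is not discarded but ranks below any finite competitor. When a
trio scores below the corresponding single-parent pair (the other parent
replaced by $FF'$), the pair score is used and that parent is declared
missing. Per offspring, resolved candidates are ranked; an assignment is
confident when the best score exceeds LOD 3 and beats the runner-up with a
different effective parent pair by more than 3 ($\delta$). Exact ties are
broken lexicographically so rankings are reproducible. Exclusion instead
counts markers where $\mathrm{sum}((T_sT_d')\circ D_o) = 0$ and accepts the
unique minimum if it is at most 0 (strict) or 3 (lenient) mismatches.

## Constrained pedigree reconstruction

Shrimp reproductive biology makes more than one or two mates per parent
unlikely within a spawning window, so the best per-offspring assignments
are reconciled into full-sib (one mate per parent), half-sib (two mates) or
unrestricted pedigrees. The search samples many random greedy pedigrees:
offspring are visited in uniformly random order and each takes its
highest-LOD feasible option; a family whose partner is missing still
occupies one mating slot of the named parent, and offspring with no
feasible positive option contribute LOD 0 as both-parents-missing. The best
of `restarts = 5000` samples is kept (desk-scale analyses in this package
use a few hundred restarts; on well-separated data the optimum is typically
found within the first few). Each restart draws from its own stream derived
from the master seed, so runs are reproducible and restart-parallelisable,
and equal-LOD options are tie-broken uniformly at random *within* a restart
— that randomness is what the search relies on. Relaxing the constraint
(1 → 2 → unlimited mates) can only grow the feasible set, so the best total
LOD is non-decreasing, a property the test suite checks along with
equivalence to exhaustive enumeration on small instances.

The search consumes *resolved* scores (single-parent fallback already
applied). Because every pure pair option is itself in the option list and is
never more constrained than the trios it dominates, greedy selection over
the combined list reproduces the resolve-then-rank behaviour.

## Pooled samples

For a pooled assay the allelic proportion is mapped to a B-allele frequency
through the piecewise-linear interpolation anchored at the calibrated
cluster means: 0 at $\mu_{AA}$, 0.5 at $\mu_{AB}$, 1 at $\mu_{BB}$, clamped
outside. The Welch statistic of the containing interval ($\tau_A$ if
$p \le \mu_{AB}$, else $\tau_B$) measures how trustworthy that estimate is.
An individual-based benchmark $f^*$ applies the same map to each pool
member's own proportion and averages.

Family contributions to a pool solve a weighted non-negative least-squares
problem: $X$ holds each family's expected offspring allele frequency per
SNP, $(T_{sire}[B]+T_{dam}[B])/2$ from the parents' genotype matrices
(structurally missing parents contribute the population frequency; missing
cells are filled with the neutral 0.5, missing $y$ with 0.5, missing
weights with 1), $y$ is the pooled estimate, and weights are $\tau^2$.
Rows are scaled by $\sqrt{w}$ and the system is solved under
$\beta \ge 0$ (`pracma::lsqnonneg`); non-negativity is the meaningful
relaxation of strict positivity, since zero is the natural boundary for a
family absent from the pool. The raw solution sums close to but not exactly
1 and is rescaled, $\hat\beta = \beta^*/\sum\beta^*$.

## The synthetic-data generator

Because raw two-channel assay tables of this kind are not publicly
deposited, the package ships a generator whose defaults emulate the study
system it was built for: a 58-SNP usable panel with B-allele frequencies
U(0.2, 0.5); heterogeneous cluster geometry (AA means U(0.02, 0.15),
off-centre heterozygote means U(0.35, 0.65), BB means U(0.85, 0.98),
class SDs U(0.01, 0.03)); adjusted intensities U(5, 15) against the
3.0-unit failure threshold; a 15% platform call-failure rate (matching the
observed share of uncalled assays) and 2% whole-assay dropout; 166
candidate sires and 124 candidate dams with 40 full-sib families of 5
genotyped offspring (~200, as in the study); and pools of 18–26 members
drawn at random from the offspring, with truncated Gaussian noise
(SD 0.03) added to pooled proportions. Parent genotypes are
Hardy–Weinberg draws; offspring inherit one allele per parent uniformly;
assay areas are synthesised by inverting the polar transform exactly, so a
noiseless round trip reproduces proportions to machine precision; pooled
proportions invert the piecewise frequency map at the panel's true means.

What the generator does *not* emulate: non-normal cluster shapes, plexing
or batch effects, sample swaps and DNA-quantity differences between pooled
individuals, and — importantly — unequal family sizes. Real hatchery
cohorts are strongly unequal (single families can make up a third of a
pool), which widens the spread of true contributions and makes
contribution recovery *easier* than under the generator's equal families.
Passing simulation tests therefore demonstrates correctness of the
machinery under controlled geometry, not field accuracy on any particular
platform.

## Numerical and design choices

* Cluster SDs use the $n-1$ sample estimator, floored at $10^{-3}$.
* Genotype densities: log-space with max-subtraction; full underflow gives
  a missing genotype rather than a spurious uniform one.
* Zero trio likelihoods propagate as $-\infty$ LOD sentinels.
* Mate counting: distinct families define mates; `(s1, missing)` and
  `(s1, d2)` give `s1` two mates — the conservative reading.
* Equal-scoring search options are permuted only when ties actually occur,
  keeping restart loops cheap.
* The allele-frequency fallback for a SNP with no reference data is
  (0.5, 0.5) with a warning, and only warns when such a SNP carries
  genotype data.
* Desk-scale problem sizes used throughout the tests (a few hundred
  offspring, thousands of candidate pairs, hundreds of restarts) were
  chosen so the whole suite exercises study-scale geometry in about two
  minutes.

## Known limitations

* With ~58 SNPs and pools containing members of a dozen or more families,
  family contributions are weakly identified: each family typically places
  only one or two realized offspring in a pool, and the Mendelian sampling
  gap between those realizations and the parental expectation in $X$
  dominates the error. Under the generator's equal-family pools of 24 from
  12 families, the correlation between estimated and true contributions is
  typically around 0.75 (about 0.8 even with noiseless pooled assays, and
  about 0.94 if $X$ could be built from the realized member genotypes).
  Contribution estimates from panels of this size are useful for ranking
  large contributors, not for precise proportions.
* The error model is per-SNP, not per-sample; sample swaps and tagging
  errors are outside its scope.
* Genotype clusters are modelled as normal; platforms with asymmetric or
  heavy-tailed clusters would need a different density in the same matrix
  framework.
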