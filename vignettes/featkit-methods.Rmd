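---
title: "featkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{featkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(featkit)
```

## The problem

G-protein-coupled receptors (GPCRs) are seven-transmembrane receptors whose
functional annotation is organized as a ragged hierarchy: a sequence is first
a GPCR or not, then belongs to a family, a subfamily, and — for some branches
only — a sub-subfamily and a subtype. Because solved GPCR structures are
scarce while primary sequences are plentiful, the practical task is
alignment-free classification from sequence alone. featkit implements one
complete pipeline for this task: a fixed 1497-dimensional sequence descriptor,
principal component reduction, and a cosine-similarity nearest-prototype
classifier applied level by level down the hierarchy, with leave-one-out
accuracy as the evaluation instrument.

Nothing in the pipeline is specific to GPCRs — any hierarchical (or flat)
protein-class labeling over FASTA input works — but the defaults (maximum
lag 30, weighting factor 0.1, 32 retained components) are the canonical
choices for this application.

## The descriptor vector

Each sequence of length $L \ge 31$ over the 20 standard residues is mapped to
1497 numbers in six fixed blocks:

| block | length | content |
|---|---|---|
| AAC | 20 | residue frequencies $n_A(i)/L$ |
| DC | 400 | dipeptide frequencies $n_D(i)/(L-1)$ |
| AD | 720 | 3 autocorrelation kinds × 8 property scales × lags 1..30 |
| GD | 147 | 7 grouping schemes × 21 composition/transition/distribution values |
| SD | 160 | 2 distance matrices × (30 coupling numbers + 50 quasi-sequence-order values) |
| PseAAC | 50 | composition + 30 correlation tiers from 3 scales |

Ordering within blocks is alphabetical by one-letter code (first letter major
for dipeptides); lag/rank indices run 1..30; the Grantham matrix precedes the
Schneider–Wrede matrix. Any fixed order is valid as long as it is declared;
this one is frozen in `feature_names()`.

**Autocorrelation.** Property scales are standardized to mean 0 and
*population* (divide-by-20) standard deviation 1 before use — the population
form is deliberate and `standardize_property()` is idempotent. With
$P(R_i)$ the standardized value at position $i$:
normalized Moreau–Broto $\mathrm{NMB}(d) = \frac{1}{L-d}\sum_i P(R_i)P(R_{i+d})$;
Moran $\mathrm{MA}(d)$ centers by the along-sequence mean $\tilde P$ and divides by
$\frac{1}{L}\sum (P(R_i)-\tilde P)^2$; Geary $\mathrm{GA}(d)$ uses squared
differences over $2(L-d)$ and the $\frac{1}{L-1}$ variance. The differing
$1/L$ vs $1/(L-1)$ denominators are implemented exactly as printed in their
defining formulas, not harmonized. Because Moran and Geary use standardized
residue values, they are invariant to affine rescaling of the raw scale (a
tested property).

**Global (CTD) descriptors.** The sequence is recoded into 3 symbols by a
property grouping; composition, transition and distribution are reported on
the percent scale. Transition counts adjacent positions whose symbols differ,
one feature per unordered pair. Distribution reports positions of the first,
25%, 50%, 75% and 100% occurrence of each symbol, divided by $L$; the
quantile occurrence index is $\max(1, \lfloor q \cdot n \rfloor)$, the rule
that reproduces the canonical two-symbol worked example exactly.

**Sequence-order descriptors.** The rank-$j$ coupling number is
$\tau(j) = \sum_i d(R_i, R_{i+j})^2$; quasi-sequence-order divides
composition and $\omega \tau$ by the shared denominator
$\sum f + \omega \sum \tau$ (default $\omega = 0.1$), so each 50-vector sums
to 1. The $\sum f$ term is identically 1 but is computed verbatim rather than
simplified away. PseAAC replaces $\tau$ by tier factors
$\theta(d) = \frac{1}{L-d}\sum_i \Theta(R_i,R_{i+d})$ with $\Theta$ the mean
squared difference of standardized hydrophobicity, hydrophilicity and
side-chain mass.

### Numerical choices and degenerate inputs

* **Constant property signal** (e.g. a homopolymer): the Moran and Geary
  denominators vanish; the value is defined as 0 — the natural limit of "no
  variation, no measurable autocorrelation". NMB needs no such rule.
* **Minimum length 31**: every lag/rank sum for $d = 1..30$ has at least one
  term. Shorter sequences are rejected rather than silently padded.
* **Nonstandard residues** (B, Z, X, U, O, J): rejected by default after
  uppercasing; `sanitize = "drop"` removes them instead. Silent substitution
  would corrupt the composition blocks.
* **Absent CTD symbol**: its five distribution values are 0, keeping the
  vector length fixed.
* All unit-sum and block-length invariants are asserted on every extraction.

### Embedded constants

The 20-value property scales are not printed in the method's defining
sources; featkit embeds them from the published scales whose names and value
ranges match exactly (AAindex entries CIDH920105, BHAR880101, CHAM820101,
CHAM820102, CHOC760101, BIGC670101, CHAM810101, DAYM780201 for the eight
autocorrelation scales; the Tanford hydrophobicity, Hopp–Woods hydrophilicity
and side-chain-mass scales for PseAAC). Each table carries a `source_tag` and
is validated against its documented range at load time. The three-group CTD
partitions follow Dubchak et al.; residue C is placed in group 1 of the
van-der-Waals-volume scheme, where its numeric value (2.43 ≤ 2.78) belongs —
some circulating implementations misplace or omit it.

The Grantham chemical distance matrix is the published one (190 pairs,
minimum 5 for Leu–Ile, maximum 215 for Cys–Trp). The Schneider–Wrede
physicochemical distance matrix could not be sourced offline; the shipped
file `dist_schneider_wrede_synthetic.tsv` is a **documented synthetic
reconstruction**: the root-mean-square distance over the standardized
hydrophobicity/hydrophilicity/side-chain-mass scales, rescaled to a unit
maximum. It satisfies every structural requirement of the original
(symmetry, zero diagonal, range [0, 1]); absolute values of the affected SD
features differ from implementations that embed the original table.

One printed value in the canonical CTD worked example is internally
inconsistent: the transition value is given as 72.14 alongside its own
formula $(21/29) \times 100.00$, which equals 72.41. featkit reproduces the
formula; the tests assert 72.41 and treat 72.14 as a digit transposition.

## Principal component analysis

Feature columns are standardized with the sample ($n-1$) variance, making the
analysed matrix $\frac{1}{n-1}Y^\top Y$ the correlation matrix (trace $p$,
another tested invariant). For $n - 1 < p$ — the usual regime at $p = 1497$ —
the eigenpairs are computed through the thin SVD of $Y$, which is identical
mathematics at a fraction of the cost and is cross-checked in the tests
against a dense independent eigendecomposition. Only the
$k = \min(n, p)$ identifiable components are stored.

Deterministic details: eigenvector signs are fixed by making each vector's
largest-magnitude entry positive; zero-variance columns are standardized to
all-zeros with a warning and carry no loading weight; eigenvalues are clamped
at 0 against roundoff.

The retained dimension defaults to $m = 32$, the canonical accuracy-selected
value. `select_m()` reproduces that selection protocol on any labeled
dataset: jackknife overall accuracy per candidate $m$, smallest maximizer
wins (parsimony tie-break). The sweep shares one leave-one-out pass — per
fold the PCA is fitted once at $\max(m)$ and predictions are recomputed per
truncation — which is mathematically identical to sweeping
`jackknife_evaluate()` but roughly $|m\text{-range}|$ times cheaper.

Feature influence is summarized by $w_j = \sum_{i=1}^{m} E_{ij}^2$
(`contribution_weights()`), which sums to $m$ by column orthonormality;
`block_contributions()` averages it over the six descriptor blocks.

## Intimate sorting and the cascade

Classification is nearest-prototype under cosine similarity
$\Phi(P, P_i) = P \cdot P_i / (\lVert P \rVert \lVert P_i \rVert)$: the query
takes the label of the highest-scoring training vector. Ties — detected with
an absolute tolerance of $10^{-12}$, since exact float equality is
meaningless — are resolved by a uniform seeded draw, the pipeline's only
stochastic element. Zero-norm vectors are rejected, not defaulted: $\Phi$ is
undefined there and a zero-norm projection signals an upstream problem.

The hierarchical classifier (`train_hierarchy()`) is a tree of independent
nodes. Each node owns its *own* PCA model (fitted on its training subset)
and its own projected prototypes; a child node exists for every predicted
label that carries deeper annotations. Prediction extracts features once and
re-projects per node, stopping when no child exists — immediately after a
level-1 non-target call, or at a ragged branch end. During evaluation,
per-level accuracies are computed on true parents (matching per-level
reporting conventions), while `predict_hierarchy()` necessarily conditions
on predicted parents.

## Jackknife evaluation

`jackknife_evaluate()` holds out each sample in turn. By default
(`pca_scope = "per_fold"`) the PCA is refitted on the $n-1$ training samples
inside every fold, so the held-out sample contributes nothing to the
projection; `pca_scope = "global"` provides the fit-once alternative for
fidelity with protocols that fitted PCA on the full dataset before
cross-validation. Per-class accuracy is $C(i)/\mathrm{Tot}(i)$ and overall
accuracy pooled counts, both in percent. Singleton classes are evaluated
(and necessarily missed — their only exemplar is held out) and flagged
rather than dropped. Fold tie-break seeds are derived from the user seed by
a multiplicative hash of the fold index, so results do not depend on
execution order; row-order invariance holds whenever no exact similarity
ties occur, which is the generic case for continuous features.

## The synthetic data generator

No external database is touched; `generate_fixtures()` produces the labeled
datasets for all tests. Its stated world, chosen once: 30 sequences per
terminal class (the size used by the separability acceptance check), lengths
drawn uniformly from 100–400 residues (desk-scale, receptor-like), and a
composition bias of 0.5 — each terminal class concentrates half its residue
mass uniformly on 4 class-specific dominant residues (disjoint across up to
five classes), the rest uniform background. An optional `autocorr_bias`
plants lag-1 structure by letting each residue copy its predecessor with
that probability. The class tree mirrors the ragged target hierarchy: the
first level-1 class descends (target branch), the others stop, and at deeper
levels the last class terminates early.

What the generator emulates: multi-class composition signal strong enough
for perfect nearest-prototype separation, chance-level behaviour when the
bias is 0, hierarchical ragged labels, and reproducibility from a single
seed. What it does **not** emulate: real GPCR sequence statistics —
homology clusters, domain architecture, length/composition covariation,
transmembrane periodicity. A green parameter-recovery test therefore
establishes that the pipeline's machinery is correct (features separate what
they should, the cascade routes correctly, jackknife counts honestly); it
does not establish benchmark accuracy on curated receptor databases, which
require external snapshots and redundancy filtering out of scope here.

## Known limitations

* The Schneider–Wrede block uses the synthetic stand-in matrix described
  above; rankings that depend on its absolute values are not comparable
  across implementations.
* Exact per-residue property values for the embedded scales are validated
  against published ranges, not against an unavailable original table dump;
  descriptor values may differ in detail from other implementations while
  all structural invariants hold.
* `pca_scope = "global"` leaks held-out information into the projection by
  construction; it exists for protocol fidelity, and the leakage-free
  per-fold mode is the default.
* The classifier outputs hard labels only; scores are cosine similarities,
  not calibrated probabilities.

## A worked run

```{r example, eval = FALSE}
fx <- generate_fixtures(fixture_spec(n_classes = 4, sequences_per_class = 30,
                                     seed = 1))
X <- extract_features_matrix(fx$sequences)
rep <- jackknife_evaluate(X, fx$labels$level1, m = 32, rng_seed = 1)
print(rep)
```

The same pipeline is available from the shell through `inst/cli/featkit`
(`fixtures`, `extract`, `train`, `predict`, `evaluate`, `select-m`,
`dump-constants`).
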