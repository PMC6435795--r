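---
title: "Consensus ranking for docking-based virtual screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus ranking for docking-based virtual screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecrank)
```

## The problem

A docking-based virtual screen scores every molecule of a library against a
protein target with one or more docking programs and ranks them, hoping that
true ligands accumulate at the top of the list. Individual scoring functions
are trained on different data and built on different approximations, so
their performance is system-dependent and their outputs correlate poorly
with each other: a molecule ranked near the top by one engine may sit deep
in another engine's list. Consensus scoring combines the per-program results
into a single hit list that is less exposed to any single program's failure
modes. This package implements one family of such combinations around
*Exponential Consensus Ranking* (ECR), together with the five classical
baselines it is usually compared against, the merging-and-shrinking
procedure for receptor ensembles, and the standard retrieval metrics.

## The consensus strategies

Let $r_i^j$ be the rank of molecule $i$ in program $j$ (rank 1 = best) and
$s_i^j$ its raw score, over $n$ programs.

**ECR** assigns each molecule

$$P(i) \;=\; \frac{1}{\sigma} \sum_{j=1}^{n} \exp\!\left(-\frac{r_i^j}{\sigma}\right),$$

and ranks by descending $P(i)$. The parameter $\sigma$ is the expected value
of the exponential kernel: it sets how many top molecules of each program
contribute appreciably. Because the kernel is steep and the contributions
are summed, one excellent rank outweighs several mediocre ones — a molecule
ranked first by a single program and poorly by the rest still scores higher
than a uniformly mediocre molecule. ECR therefore behaves as a conditional
"or" over programs, where averaging behaves as a soft "and". The $1/\sigma$
prefactor is a common positive factor; dropping it never changes the
ranking (this is a property test in the suite).

The baselines are: **RbR** (rank-by-rank), the mean of $r_i^j$; **RbV**
(rank-by-vote), the number of programs ranking the molecule within the top
$x\%$; **RbN** (rank-by-number), the mean raw score; **AASS**, the mean of
per-program min–max–rescaled scores; and the **Z-score** consensus, the mean
of per-program standardized scores. The first three consume only ranks and
are invariant under any strictly monotone transform of a program's scores;
AASS and Z-score are invariant under per-program positive affine transforms;
RbN is invariant under neither and is systematically biased toward programs
whose scores are numerically more negative — the suite carries a witness
instance where a $-1000$ offset on one program dictates the RbN ordering.

A **random scoring function** (i.i.d. standard normal scores) is included as
a negative control for a broken engine.

## Parameters and conventions

* **Score direction** is per-table configuration, default `lower` (all
  common docking engines emit more-negative-is-better energies).
* **Threshold resolution.** Percent-mode $\sigma$ resolves to
  $\max(1, \operatorname{round}(x/100 \cdot N))$ molecules; the RbV vote
  cutoff to $\max(1, \lfloor x/100 \cdot N \rfloor)$. Both default to 5% of
  the dataset, the conventional setting. $\sigma$ is held constant across
  programs by default; a named per-program vector is accepted.
* **Raw-score ties** within one program are broken by ascending molecule id,
  so every per-program rank table is a strict permutation of $1..N$ — the
  exponential kernel needs one integer rank per molecule.
* **Consensus-score ties** are detected exactly for integer vote counts and
  at relative tolerance $10^{-12}$ for real-valued scores; tied molecules
  form a *tie group* whose provisional internal order is again ascending
  molecule id, so every result is deterministic before any shuffling.
* **Z-score** uses the population (not sample) standard deviation; with
  $N$ in the thousands the distinction is negligible, and the population
  form matches the definition as a score rescaling rather than an estimator.
* **Missing molecules.** Programs occasionally fail to score molecules.
  `align_programs()` offers `worst_rank` (default: missing molecules are
  appended at the bottom of that program's ranking in id order, keeping the
  molecule set complete) and `intersect` (keep only molecules scored by all
  programs, re-ranked). Both semantics are legitimate; the default
  preserves information about molecules most programs did score.

## Tie-shuffling uncertainty

Any metric that cuts the ranked list at a threshold is undetermined when a
tie group straddles the cut. `shuffle_evaluate()` permutes the order inside
every tie group uniformly at random (cross-group order stays fixed), 20
times by default, and reports the mean and standard deviation of each
metric. The suite checks the shuffle mean against an exact enumeration of
all within-group orderings on a small instance. For RbV — whose score takes
at most $n+1$ values, so a single vote count can cover most of the dataset —
this uncertainty is large; for ECR only molecules with coinciding
exponential sums (in practice the poorly ranked tail, which at extreme
small $\sigma$ underflows to an exact zero score) are affected. The contrast
is asserted statistically over 20 screens in the acceptance suite.

The deterministic ROC implementation handles tie groups by letting all
members enter at one threshold step, drawing a diagonal segment; the
trapezoidal area then equals the Wilcoxon–Mann–Whitney pairwise statistic
with ties counted $1/2$ (checked against a brute-force pair count and
against pROC).

## Merging and shrinking for receptor ensembles

With several structures of one target, the merging-and-shrinking procedure
keeps each molecule's best rank (rank variant) or best score (score
variant) across structures, per program. The merged best-rank keys are not
a permutation, so the rank variant re-ranks them (ties by molecule id); the
alternative of feeding the raw best-rank integers into the consensus
formulas gives the same ordering for strictly monotone consumers but would
leave the output outside the rank-table contract, so re-ranking was chosen.
The score variant deliberately does not correct per-structure offsets; the
suite carries a witness where a $-50$ offset on one structure makes the
merged table identical to that structure's scores. This hazard is why the
pipeline pairs rank-level merging with rank-based strategies and
score-level merging with score-based strategies (`ms_mode = "auto"`), and
refuses incompatible forced pairings.

## The synthetic screen generator

Real benchmark screens require docking engines and curated decoy libraries;
the generator replaces them with a transparent statistical stand-in. Every
molecule draws a latent affinity $a_i = \mu \cdot 1[\text{ligand}] +
\varepsilon_i$; program $j$ reports $s_i^j = \text{offset}_j +
\text{scale}_j(-q_j a_i - (1-q_j) e_{ij})$ with noise $e_{ij}$ mixing a
shared channel (inter-program correlation $\rho$) and a private one.

Defaults — the reference condition used by the tests and the acceptance
script — are $N = 2000$ molecules, 10% ligands, six programs with qualities
$(0.8, 0.7, 0.6, 0.5, 0.4, 0)$ (the last a broken engine, mirroring the
random-scoring-function control), $\rho = 0.3$, unit scales and zero
offsets. The separation $\mu = 1.227$ was calibrated once, analytically,
so that a quality-0.8 program attains ROC-AUC $\approx 0.8$ via
$\mathrm{AUC} = \Phi\!\big(q\mu / \sqrt{2(q^2\sigma_a^2 + (1-q)^2)}\big)$;
the informative programs then span AUC $\approx 0.69$–$0.80$, a realistic
range for docking engines, and the screens reproduce the qualitative
rank–rank dispersion of real program pairs.

What the generator does *not* emulate: heavy-tailed and skewed docking-score
distributions, chemotype clustering of ligands, analogue bias in decoy
selection, and pose-level failures. Tests passing on synthetic screens
therefore demonstrate the correctness and the comparative statistical
behaviour of the consensus machinery, not absolute enrichment levels on any
real target.

## Numerical choices and degenerate inputs

* Empty tables, non-finite scores, duplicated ids, mixed directions within
  a program, constant-score tables (AASS) and zero-variance tables
  (Z-score) are rejected with targeted errors.
* Duplicate ids in an input file (tautomers, repeated poses) may be
  collapsed to the best-scoring entry per parent molecule
  (`collapse = "best"`, `collapse_variants()`), the standard convention for
  tautomer handling.
* Enrichment factors use top-list size $N^{x\%} = \max(1, \lfloor x/100
  \cdot N \rfloor)$; the enrichment curve uses the same rule so that
  $\text{recovered}(x) = \mathrm{EF}_x \cdot x$ holds exactly at thresholds
  where $x N / 100$ is whole. The curve grid defaults to 0.5% steps.
* All randomness (generator, random scoring function, shuffles) flows
  through explicit integer seeds; identical seeds give byte-identical
  output.

## Scale of the validation suite

The statistical assertions run on screens of $N = 2000$ (the reference
condition) or smaller, with 20-screen replicates for the shuffle-contrast
and robustness checks and 20 shuffles per screen, matching the protocol's
defaults; enumeration oracles run on instances of at most six molecules.
These sizes make every distributional claim in the test suite cheap to
recompute from scratch.

## Known limitations

* The sigma-independence of ECR is reproduced here at the enrichment-factor
  level (EF2 varies by well under 20% across $\sigma = 1$–10% of the
  dataset on the reference screen). Deeper in the list the picture is
  sharper: when a broken program is present, its pure-noise contribution
  carries $\sigma$-dependent weight, so the ordering of the union of
  top-decile molecules correlates only moderately (Spearman $\approx$
  0.45–0.7) between $\sigma = 1\%$ and $10\%$; with six informative,
  well-correlated programs the same correlation exceeds 0.99. The
  acceptance suite states the strict ordering-level bound and records the
  measured value rather than weakening the check.
* Score-level merging inherits offset hazards by design (see above); no
  offset correction is attempted.
* No pose-level consensus: the package combines one score per molecule per
  program, not docking poses.
* BEDROC, RIE and other early-recognition metrics are out of scope.
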