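---
title: "Genomic prediction and low-density SNP panel design with ldpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction and low-density SNP panel design with ldpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldpanel)
```

## The problem

High-density SNP assays make genomic selection possible: marker effects
estimated once in a large, progeny-tested reference population predict
breeding values for young animals from their genotypes alone (the *direct
genomic value*, DGV). But high-density genotyping of every selection
candidate is expensive. If a few hundred to a few thousand well-chosen
markers recover most of the accuracy of the full assay, routine genotyping
can move to a much cheaper low-density chip.

`ldpanel` implements the full workflow for studying that trade-off:

1. fit whole-genome prediction equations with two engines — SNP-BLUP
   ridge regression and partial least squares regression (PLSR);
2. rank all markers per trait by backward elimination;
3. build low-density panels by four strategies (trait-specific top
   markers, or a single evenly spaced panel chosen by index rank or minor
   allele frequency);
4. evaluate panels by validation-set accuracy, relative to the
   full-density accuracy, overall and within groups defined by pedigree
   (animals with or without a sire in the training set);
5. simulate pedigreed populations with linkage disequilibrium so the whole
   stack is testable end-to-end without proprietary industry data.

## Prediction engines

### SNP-BLUP ridge regression

With $N$ training animals and $p$ SNP coded $0/1/2$ in the incidence
matrix $\mathbf{X}$, the intercept $\hat\mu$ and marker effects
$\hat{\mathbf{b}}$ solve the mixed model equations

$$
\begin{bmatrix} N & \mathbf{1}'\mathbf{X} \\
\mathbf{X}'\mathbf{1} & \mathbf{X}'\mathbf{X} + \mathbf{I}\lambda
\end{bmatrix}
\begin{bmatrix} \hat\mu \\ \hat{\mathbf{b}} \end{bmatrix}
=
\begin{bmatrix} \mathbf{1}'\mathbf{y} \\ \mathbf{X}'\mathbf{y} \end{bmatrix},
$$

with one common penalty $\lambda$ for all SNP. This is BLUP of marker
effects under a common normal prior, with $\lambda = \sigma^2_e/\sigma^2_b$.
Predictions for new animals are $\mathrm{DGV} = \mathbf{X}_{new}\hat{\mathbf{b}}$
(the intercept is dropped; accuracy is a correlation and therefore
shift-invariant).

Numerical choices:

* The system is solved **matrix-free** with a preconditioned conjugate
  gradient (PCG): only products with $\mathbf{X}$ and $\mathbf{X}'$ are
  formed, never $\mathbf{X}'\mathbf{X}$, so memory is $O(Np)$ and each
  iteration costs two matrix-vector products.
* Preconditioner: Jacobi (the MME diagonal, $[N;\ \mathrm{diag}
  (\mathbf{X}'\mathbf{X})+\lambda]$). Convergence is declared at a
  relative residual of $10^{-11}$ (default `tol`), which keeps the
  solution within $\approx 10^{-7}$ of a dense direct solve even for
  ill-conditioned instances; inner cross-validation fits use a looser
  $10^{-8}$ for speed. The iteration cap is 5000; hitting it raises an
  error carrying the residual history rather than returning a bad
  solution.
* Optional per-animal weights (e.g. daughter counts) turn every
  $\mathbf{1}$/$\mathbf{X}$ cross-product into its weighted version. They
  are off by default: with uniformly reliable progeny-test phenotypes,
  weighting has little effect.

$\lambda$ is tuned by $k$-fold cross-validation (default $k=10$) with a
golden-section search on $\log_{10}\lambda$. The fold assignment is a
deterministic function of `(n, k, fold_seed)` and is shared by every
$\lambda$ evaluated (common random numbers), so the CV profile is smooth
and the search reproducible. The default bracket is
$[10^{-3}p,\ 10^{3}p]$ — scaling by $p$ keeps the per-SNP shrinkage
comparable across panel sizes — and the default objective is mean squared
prediction error (a predictive-correlation objective is available).

### Partial least squares regression

PLSR builds latent components $\mathbf{t} = \mathbf{X}\mathbf{w}$ with
maximal covariance with the response, mutually orthogonal by
construction. We use the orthogonal-scores (NIPALS-type) algorithm with
X-only deflation; for a univariate response this is equivalent to SIMPLS,
and with as many components as the rank of centered $\mathbf{X}$ it
reproduces the ordinary least squares fit — which is exactly how the
implementation is tested. $\mathbf{X}$ and $\mathbf{y}$ are centered
internally (latent-component extraction requires it); coefficients are
back-transformed to the raw dosage scale with the centering absorbed into
the intercept, so both engines produce comparable DGV. The number of
components is chosen by the same fixed-fold cross-validation, ties going
to the smaller count.

## Marker ranking by backward elimination

A marker's regression coefficient depends on the other markers in LD with
it, so a single full fit does not rank markers fairly. The ranking
procedure therefore iterates: fit the model on the surviving SNP
(re-tuning $\lambda$ or the component count at each step, on the same
folds), order by $|\hat b_j|$, and drop the lowest-ranked down to the
next scheduled subset size.

The default schedule starts at the full panel, first retains 40,000
(when starting above that), then steps of 2,000 down to 10,000, of 500
down to 1,000, of 100 down to 300, and of 20 down to 100. For smaller
panels the schedule starts at the largest rung at or below $p$; custom
breakpoints are a configuration option. SNP dropped at a step receive
ranks worse than all survivors, ordered within the batch by their
coefficient magnitude at drop time; exact ties (rare with continuous
coefficients) break by genome coordinate and then SNP id, so the ranking
is fully deterministic.

## Low-density panel strategies

* **Trait-specific top markers** — the first $n$ entries of the trait's
  ranking.
* **Evenly spaced panels** — the autosomes are concatenated in map order
  onto a cumulative coordinate of length $L$ (0-based, half-open
  intervals; chromosome junctions may fall inside a segment), boundaries
  at $iL/n$. Within each segment the panel takes the single SNP best
  ranked for a profit index (ASI or APR) or with the highest training-set
  minor allele frequency. The interval reading of "evenly spaced" is a
  deliberate design choice: segments are coordinate intervals, with no
  snapping of interval ends to marker positions. Empty segments are
  reported as a shortfall rather than silently borrowed from neighbours
  (an optional backfill takes the globally best unselected SNP).
* MAF is always computed on the **training set only**, since panel
  selection must not look at validation animals.

Cross-trait overlap of trait-specific panels is summarized as the
percentage of markers shared by every combination of $k \ge 2$ traits.

## Selection indices

The profit indices are fixed linear combinations of component breeding
values with the published economic weights:

* ASI $= 3.8\,\mathrm{protein} + 0.9\,\mathrm{fat} - 0.048\,\mathrm{milk}$
* survival $= 0.5\,\mathrm{likeability} + 1.8\,\mathrm{overall\ type} +
  3.0\,\mathrm{udder\ depth} + 2.2\,\mathrm{pin\ set}$
* APR $=$ the ASI terms $+\ 1.2\,\mathrm{milking\ speed} +
  2.0\,\mathrm{temperament} + 3.9\,\mathrm{survival} +
  0.34\,\mathrm{cell\ count} - 0.26\,\mathrm{live\ weight} +
  3.0\,\mathrm{daughter\ fertility}$

APR references the survival *index* as a component; the package resolves
index components recursively, so survival is computed first.

## The population simulator

The real data behind this methodology (industry progeny-test records and
proprietary genotypes) cannot ship with a package, so `ldpanel` includes
a forward-in-time simulator whose defaults are chosen to emulate the key
features of such data:

* **LD from drift.** Founder haplotypes start in linkage equilibrium
  with allele frequencies drawn from Uniform(0.05, 0.5); LD is generated
  by random mating in a finite bottleneck population (default 100
  diploids for 50 generations) before the recorded pedigree begins.
  Recombination follows Haldane's map function at 1 cM/Mb. Smaller
  bottlenecks give more drift and more LD — a property-tested knob.
* **Pedigree.** Discrete generations; a limited number of sires per
  generation (progeny-test style), all females used as dams. An optional
  `unknown_sire_rate` leaves a fraction of sires unrecorded (the genotype
  still descends from the true sire), producing the "no sire in
  training" validation group found in real data.
* **Trait architecture.** A shared pool of `n_qtl` causal loci is
  simulated alongside the markers and — by default — excluded from the
  genotyping panel, so markers predict through LD only, as on a real SNP
  chip where causal variants are untyped (`qtl_in_panel = TRUE` restores
  typed QTL; with typed QTL, marker selection can recover the causal loci
  themselves and a small panel can out-predict the full one, which chip
  data cannot do). Each direct trait draws independent normal effects on
  the pool, rescaled so the founder-generation TBV variance equals
  $\sigma^2_g$ exactly. A major-gene option assigns a chosen fraction of
  $\sigma^2_g$ to one QTL (a DGAT1-like gene at 30% is the motivating
  case) with the remainder split equally.
* **Phenotypes.** Deregressed proofs are emulated as
  $y_i = \mathrm{TBV}_i + e_i$ with
  $e_i \sim N\!\big(0, \sigma^2_g (1-r^2_i)/r^2_i\big)$ and the
  progeny-test reliability $r^2_i = (n_i h^2/4)/(1 + (n_i-1)h^2/4)$ from
  the record count $n_i$. The true deregression machinery of national
  evaluations is out of scope; the reliability model is an explicit,
  replaceable stand-in (`reliability_fn`), because published analyses do
  not pin down how proof noise scales with "equivalent daughter
  contributions". At $h^2 = 0$ the reliability is zero and the model is
  undefined; an uninformative phenotype must be requested explicitly with
  `pure_noise = TRUE`, which is also the null-calibration pathway used in
  the tests.
* **Traits are simulated independently** (no genetic correlation matrix
  is imposed — published sources give none); indices are deterministic
  combinations of their components. Consequently, cross-trait overlap
  results from the simulator reflect index-component structure only, not
  pleiotropy.
* **Seeding.** One integer seed drives everything through named
  sub-streams (map, haplotypes, pedigree, effects, noise, folds), so any
  stage reproduces bit-identically in isolation.

What the simulator does *not* reproduce: the real bovine LD structure and
map, selection (matings are random), genotyping error and missingness
patterns, and between-trait genetic correlations. Passing tests on
simulated data therefore demonstrate internal correctness and the
qualitative behaviour of the methods (heritability response, subset-size
response, null calibration), not quantitative accuracy on any real
population.

## Evaluation

Accuracy is the Pearson correlation between DGV and the validation
phenotype (or the true breeding value, in simulations). A zero-variance
vector makes the correlation undefined; the package returns a flagged
`NA` with a warning instead of a fabricated zero, because real no-sire
validation groups can be as small as a dozen animals and silent zeros
would poison summaries. Relative accuracy is $100 \cdot
\mathrm{acc}_{subset}/\mathrm{acc}_{full}$, using each group's own
full-panel accuracy as its reference. Pedigree relationships use the
tabular method with inbreeding carried through the diagonal (simulated
pedigrees can inbreed), verified in tests against a gene-dropping
Monte-Carlo oracle.

## Typical problem sizes

The package's own test and demonstration runs use populations of
1,000-2,000 animals and 500-2,000 SNP with 10-100 QTL — large enough for
LD-based prediction to work clearly (full-panel validation accuracies
near 0.9 at $h^2 = 0.5$, dropping with heritability and panel size), and
small enough that the entire suite, including ten-seed replicated
studies, runs on a laptop. All replicated comparisons are paired by seed
and assessed with sign tests or rank correlations rather than a single
run's point estimate.

## A small worked run

```{r example, eval = FALSE}
sim <- simulation_config(n_founders = 250, n_generations = 3,
                         n_sires_per_gen = 15, n_chromosomes = 5,
                         snp_per_chrom = 100, n_qtl = 50, h2 = 0.4,
                         unknown_sire_rate = 0.1, seed = 1)
cfg <- run_config(simulation = sim, traits = c("asi", "apr"),
                  methods = c("rr", "plsr"),
                  subset_sizes = c(50, 150, 300),
                  schedule_breakpoints = data.frame(threshold = c(150, 50),
                                                    step = c(175, 100)),
                  schedule_floor = 50,
                  cv = cv_config(k_folds = 5, gs_tolerance = 0.1),
                  out_dir = "demo_run", seed = 42)
res <- run_pipeline(cfg)
res$summary
```

The run directory contains every artifact (genotypes, phenotypes,
pedigree, effects, rankings, subsets, per-group results, summaries) plus
`manifest.json` with the config hash, seed and per-stage status — enough
to reproduce any output exactly.

## Known limitations

* The schedule interpretation ("step size 2,000 while above 10,000", and
  so on) reproduces all the subset sizes a practitioner expects, but
  other readings of the published wording are conceivable; breakpoints
  are configurable for that reason.
* Backward elimination with per-step re-tuning is expensive at high
  density; the implementation is plain R (BLAS-bound matrix products),
  with no sparse or parallel backend.
* PLSR ranking uses coefficient magnitudes on the dosage scale, like the
  ridge ranking; no variable-importance-in-projection alternative is
  provided.
* Bayesian variable-selection engines (BayesB-style), genotype
  imputation, and blending DGV with parent averages are out of scope.
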