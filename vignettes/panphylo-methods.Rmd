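---
title: "Models and methods behind panphylo"
author: "panphylo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind panphylo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panphylo)
```

# Scope

`panphylo` re-implements, as reusable and tested functions, the
quantitative machinery used to study how a discrete metabolic trait —
the motivating case is nitrate assimilation in *Prochlorococcus* — is
gained, lost and exchanged across a microbial radiation sampled largely
through partial single-cell genome assemblies. Five analysis stages are
covered: ancestral-state inference for a binary trait, gene-content
covariation in a pangenome of partial assemblies, phylogenetic
population-divergence tests, codon-model tests of selection, and
recombination summary statistics. A synthetic-data module generates
inputs with the statistical structure each stage assumes, so the whole
pipeline can be exercised and calibrated without any external genome
data.

# Ancestral states of a binary trait

## Weighted parsimony

`sankoffParsimony()` implements Sankoff dynamic programming on a rooted
tree with an asymmetric binary cost matrix: a 0→1 change costs
`costGain`, a 1→0 change costs `costLoss`. Changes are counted per
branch irrespective of branch length, which is the convention of the
programs this reproduces. Comparative analyses of gene gain and loss
often weight gains much more heavily than losses (10:1 is a common
choice) because loss by deletion is far more accessible mutationally
than re-acquisition. Rather than breaking ties arbitrarily, the
up-pass computes, for every node and state, the best total cost of any
full reconstruction using that state, and reports *all* states that
occur in at least one most-parsimonious reconstruction. Tips with
missing states (genomes screened but not assembled, for example)
contribute zero cost for either state; they are constrained by their
neighbours, not dropped.

## The Mk model and its likelihood-ratio test

`mkLogLik()` computes the likelihood of tip data under the 2-state
continuous-time Markov (Mk) model with gain rate $q_{01}$ and loss rate
$q_{10}$, using Felsenstein pruning with the exact closed-form
transition matrix

$$P(t) = \begin{pmatrix}
1-\pi_1(1-e^{-st}) & \pi_1(1-e^{-st})\\
\pi_0(1-e^{-st}) & 1-\pi_0(1-e^{-st})
\end{pmatrix},
\qquad s = q_{01}+q_{10},\ \pi_1 = q_{01}/s .$$

`fitMk()` maximizes this over rates in $[10^{-4}, 10^3]$ (per unit
branch length) in log space, starting from a $5\times5$ log-spaced
grid; the best grid points seed quasi-Newton refinement, and the
returned optimum is never below any grid value, which makes the fit
deterministic for a fixed grid and robust to the likelihood's occasional
ridges. `compareMkModels()` fits the one-parameter symmetric model (MK1,
$q_{01}=q_{10}$) and the two-parameter asymmetric model and performs the
1-df likelihood-ratio test; because the symmetric optimum is itself a
feasible asymmetric model, the function guarantees the nesting
inequality before testing.

**Root prior.** The analyses this package follows do not state the
root-state convention of the software they used, and the fitted rates
depend on it. Both conventions are therefore offered and recorded:
`rootPrior = "equal"` (uniform over states, the default) and
`"stationary"` ($\pi$ of the fitted chain). Neither is asserted to be
"the" published setting; analyses that aim to reproduce a published
number should try both.

# Gene content in partial assemblies

Partial single-cell assemblies observe each underlying gene with
probability roughly equal to the assembly's recovery fraction. Two
consequences drive the design here:

* **Core threshold.** A gene cluster present in *every* genome is
  expected in only ~median-recovery of the assemblies, so
  `coreThreshold(n, m)` classifies a cluster as core when it appears in
  at least $\lfloor n \times m \rfloor$ genomes. Floor (rather than
  rounding) is used; the worked example $22 \times 0.87 \to 19$ fixes
  this convention.
* **Expected annotations.** Among genomes that are marker-positive by
  PCR, the number whose assembly should also contain the annotated gene
  is `round(count × median recovery)`; the shortfall of observed
  annotations against this expectation is reported by
  `concordanceStats()` as a post hoc false-negative rate. Report
  percentages are rounded half-up to integers (97%, 73% style); raw
  values are kept alongside.

`filterFlexible()` removes core clusters and clusters seen in fewer
than three genomes — both ends carry little information about
covariation — and is idempotent. `jaccardLinkage()` clusters the
remaining flexible clusters by average linkage on Jaccard distance
between genome-presence sets. `markerEnrichment()` tests each flexible
cluster for over- and under-representation among marker-positive
genomes with exact hypergeometric tails; both directions are computed
and labelled (the GUI tools this mirrors are ambiguous on sidedness)
and each direction is Benjamini–Hochberg corrected across clusters.

# Phylogenetic divergence between populations

`unweightedUnifrac()` returns the fraction of branch length leading
exclusively to one population's leaves, out of the branch length
subtending all mapped leaves, on a rooted tree (use `midpointRoot()`
first; rooting follows the midpoint of the longest leaf-to-leaf path).
`pTest()` counts the minimum number of population-label changes on the
tree (Fitch parsimony; invariant to rerooting). Significance for either
statistic comes from `permutationSignificance()`, which permutes the
leaf-to-population map holding group sizes fixed and uses the
$(k+1)/(n+1)$ estimator so a p-value can never be exactly zero; the raw
exceedance count is recoverable from it. "More extreme" means a larger
UniFrac fraction but a *smaller* change count — fewer changes mean more
phylogeographic structure. `subsamplePopulations()` draws equal-sized
subsamples per population (the published design uses 9 + 9), with
replicates as independent draws rather than a partition.

Trees for the subsamples must be supplied (or simulated); the package
does not re-implement maximum-likelihood tree inference, so published
p-values that depend on a specific inferred tree are reproduced in
distribution, not digit-for-digit.

# Codon models of selection

`gy94RateMatrix()` builds the Goldman–Yang codon rate matrix over the 61
sense codons of the universal code: zero for multi-nucleotide changes,
and $\pi_j$, $\kappa\pi_j$, $\omega\pi_j$, $\kappa\omega\pi_j$ for
synonymous/nonsynonymous transversions/transitions, scaled to one
expected substitution per codon at equilibrium. Equilibrium frequencies
come from `f3x4Frequencies()` (position-specific nucleotide
compositions multiplied per codon and renormalized). Zero-frequency
codons are floored at $10^{-10}$ inside the rate matrix so the chain
stays irreducible; the frequencies themselves are reported exactly.

`codonLogLik()` evaluates site likelihoods by pruning with per-site
scaling (mandatory — long concatenations underflow otherwise). Site
mixtures (M1a, M2a, M7, M8) weight class-conditional site likelihoods
by the class proportions; the beta distribution of M7/M8 is discretized
into `K = 10` equal-probability categories at their conditional means,
the convention of the standard ML implementation. Branch-site model A
switches the foreground classes' rate matrix on designated branches
(`stemEdge()` marks a clade's stem). Codons containing gaps or
ambiguity codes are marginalized over every compatible codon, not
dropped.

Two design choices deserve note:

* **Branch lengths are fixed**, mirroring the published protocol of
  holding an externally estimated tree constant; a single global
  multiplier is estimated to absorb the difference between
  nucleotide-unit and codon-unit lengths.
* **"M1/M2" mean the modern M1a/M2a** ($\omega_0$ estimated, class at
  $\omega=1$). A strict-neutral variant could be emulated by fixing
  $\omega_0$; the default follows current practice since published
  near-zero $\omega$ estimates do not disambiguate the variant used.

Fits (`fitSiteModels()`, `fitBranchSite()`) run quasi-Newton
optimization on unconstrained transforms (log rates, logistic
proportions), warm-starting each model from its nested null and always
including the null's optimum among the candidates, so the nesting
inequalities $\ell(\mathrm{M1a}) \ge \ell(\mathrm{M0})$,
$\ell(\mathrm{M2a}) \ge \ell(\mathrm{M1a})$,
$\ell(\mathrm{M8}) \ge \ell(\mathrm{M7})$ and
$\ell(\mathrm{H1}) \ge \ell(\mathrm{H0})$ hold by construction for
every reported fit. `neiGojobori()` provides the NG86 counting
estimator (pathway-averaged differences, Jukes–Cantor correction) as an
independent sanity check on the ML $\omega$; note that pathway
averaging can attribute small nonsynonymous counts to histories that
contained none, so it is a directional check, not an oracle.

# Recombination statistics

The package consumes ClonalFrame-style parameter estimates — $\kappa$,
mean import length $\delta$ (bp), import divergence $\nu$ (per site)
and relative initiation rate $R/\theta$ — and derives
$\rho/\theta = 2R/\theta$ and the relative impact of recombination
versus mutation, $r/m = (R/\theta)\,\delta\,\nu$
(`recombinationSummary()`). Derived values are always recomputed from
primitives. When published r/m values are supplied the summary adds
their percent deviation with a 5% default consistency band: published
primitives are typically printed to three significant figures, and
recomputation from rounded inputs can differ from a value computed at
machine precision by a percent or two (e.g. 34.3 recomputed against a
printed 34.0).

`simulateClonalFrameAlignment()` is the generative counterpart: point
mutations arrive at $\theta$ per site per unit branch length, imports
initiate at $(R/\theta)\theta$, tracts are geometric with mean
$\delta$ (truncated at the sequence end; linear sequences), and tract
sites are substituted independently with probability $\nu$. Events on
a branch apply in time order, so overlapping imports are permitted and
the last event at a site wins — the simplest consistent generative
story, consequential only at high $R/\theta$. `realizedRmFromLog()`
divides substituted import sites by point mutations; over long
simulations it converges to $(R/\theta)\,\delta\,\nu$, which is the
property the test suite checks at $10^6$ site-branch units.

# Transport energetics

`transportFreeEnergy()` evaluates
$\Delta_r G = RT\ln([n]_I/[n]_E) + zF\Delta\Psi$ for nutrient uptake:
the scarcer the external nutrient, the higher the free-energy cost of
accumulating it, which links nutrient affinity to cellular energy flux
in macroevolutionary arguments about depth-partitioned niches. The
physical constants are fields of `transportContext()` (CODATA defaults)
so alternative unit systems can be tested rather than hard-coded.

# The synthetic-data module

The generators are first-class, tested code, and every stochastic
operation is a pure function of its inputs and a mandatory seed (the
caller's RNG state is saved and restored). What they emulate — and
deliberately do not:

* `simulateYuleTree()`: pure-birth ultrametric trees as a stand-in for
  an inferred core-marker phylogeny. Real trees are non-ultrametric and
  clade-imbalanced; nothing downstream assumes ultrametricity.
* `simulateBinaryTrait()`: the exact asymmetric 2-state chain,
  returning true internal states so reconstruction methods can be
  scored. Default study condition in the tests: 500 leaves with
  $(q_{01}, q_{10}) = (0.5, 1.0)$, chosen to produce the gain/loss
  asymmetry regime the motivating analysis reports, with enough events
  for both rates to be identifiable.
* `simulatePartialGenomes()`: independent per-gene Bernoulli retention
  at each genome's recovery fraction. Real assembly dropout is
  correlated along the chromosome and biased by amplification; the
  independence assumption is exactly what the recovery-corrected
  thresholds assume, so passing tests validate the arithmetic, not the
  dropout model.
* `simulateCodonAlignment()`: GY94 site-class mixtures; stop codons are
  structurally impossible. No indels and no among-site rate variation
  beyond the $\omega$ classes.
* `simulateTwoPopulationTree()`: "complete" glues two unit-height
  clades (reciprocal monophyly; UniFrac 1, one P-test change);
  "none" randomly interleaves labels on one tree, the null used for
  calibration of permutation p-values.

# Numerical choices and problem sizes

* Mk optimization: log-rate bounds $[10^{-4}, 10^3]$, $5\times5$ start
  grid, L-BFGS-B with an lnL tolerance near $10^{-8}$.
* Codon-model optimization: BFGS, relative tolerance $10^{-10}$, at
  most 500 iterations per start; per-site scaling in every pruning
  pass; spectral decomposition of the symmetrized generator (cached per
  $\omega$ within a fit) for matrix exponentials.
* Permutation tests default to 1000 iterations; the $(k+1)/(n+1)$
  estimator bounds the smallest attainable p at $1/(n+1)$.
* Test-suite problem sizes were chosen as the smallest at which the
  checked properties are statistically crisp: brute-force oracles run
  on 6-leaf (parsimony), 3–4-leaf (Mk likelihood) and 10-leaf
  (UniFrac/P-test) trees; parameter recovery uses 50 replicates of
  500-leaf trees; codon-model recovery uses 8 taxa × 200 codons with
  null calibration at 6 taxa × 100 codons; the r/m convergence check
  uses $10^6$ site-branch units.

# Known limitations

* Binary traits only; no covarion or hidden-rate models.
* The universal genetic code only; no Bayes empirical Bayes site
  identification in the branch-site machinery.
* ClonalFrame parameter *inference* is consumed, not reimplemented; the
  package derives and validates the summary statistics.
* Published quantities that depend on external genome data and on the
  specifics of external tree/alignment software (per-gene divergence
  tables, site-model $\omega$ values on the real alignments, exact
  permutation p-values on inferred subsample trees) are reproduced in
  mechanism and calibration, not digit-for-digit.
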