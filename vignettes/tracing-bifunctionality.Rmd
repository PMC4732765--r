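---
title: "Tracing enzyme bi-functionality: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing enzyme bi-functionality: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hisatrace)
```

`hisatrace` implements the computational chain used to trace a
bi-functional enzyme family — the HisA/PriA isomerase superfamily of
histidine and tryptophan biosynthesis — across deep evolutionary time:
sequence similarity networks over the superfamily, gene-neighborhood
screening and species-wise concatenation, alignment and trimming, Bayesian
and maximum-likelihood phylogenetics with convergence diagnostics, marginal
ancestral sequence reconstruction, active-site motif conservation, and
steady-state enzyme kinetics. Every stage runs on synthetic data with known
ground truth, so the whole chain is testable without any database access.
This vignette records the models, the tunable parameters, and the design
decisions that were genuinely open.

## The scientific setting

HisA (ProFAR isomerase, histidine biosynthesis) and TrpF (PRA isomerase,
tryptophan biosynthesis) catalyze analogous isomerizations of an
aminoaldose to an aminoketose. In Actinobacteria the trpF gene is often
missing and a single bi-functional HisA homolog, PriA, carries both
activities. Asking whether that bi-functionality is an actinobacterial
innovation or an ancient trait requires (i) surveying PriA-like features in
modern HisA enzymes — similarity networks and active-site motifs — and
(ii) reconstructing ancestral HisA sequences on a well-supported species
tree and characterizing their kinetics. The package provides each of those
steps as composable functions plus a `run_pipeline()` orchestrator.

## Substitution models and the likelihood core

Amino-acid evolution is modeled by reversible empirical models (JTT by
default, WAG optionally) with the rate matrix `Q = S diag(pi)` normalized
to one expected substitution per site per unit branch length, so branch
lengths are expected substitutions per site throughout. Transition matrices
come from the spectral decomposition of the symmetrized generator, which is
exact and cheap for arbitrary branch lengths. Optional among-site rate
heterogeneity uses the standard discrete-gamma approximation with four
equal-weight categories whose rates are category means.

Likelihoods are computed by the pruning algorithm with per-column
rescaling (log scale factors accumulated per node) and site-pattern
compression. Gaps and ambiguity codes (X, B, Z) are treated as fully
missing — their conditional likelihood is 1 for every state. The
implementation is checked three ways in the test suite: against brute-force
enumeration over all internal-state assignments on four-taxon trees,
against an independent likelihood implementation on simulated data, and
through the pulley principle (invariance under re-rooting, tolerance
1e-8).

The infinite mixture model used by some Bayesian samplers (site-specific
equilibrium-frequency classes) is deliberately not implemented; fixed
empirical exchangeabilities are sufficient for the package's
simulation-based validation and keep the sampler simple. This is a stated
simplification, not an equivalence claim.

## The synthetic-data generator

The generator defines the study conditions; its defaults are fixed once
and the tests are calibrated to them.

* **Families** evolve along Yule trees (`sample_yule_tree()`), root
  sequence drawn from the model's equilibrium, branches applying exact
  CTMC endpoint substitutions. Indels are a Poisson process at
  `indel_rate` events per site per unit branch length, insertion:deletion
  1:1, lengths `1 + Geometric(p = 0.3)`, placed uniformly; inserted
  columns are threaded consistently into the global alignment so the true
  alignment — including every ancestral sequence — is known exactly.
* **Genomes** (`make_genomes()`) place hisA/hisF/hisH as strict neighbors
  (random internal order, one strand) in a configurable fraction of
  species; the rest scatter the markers with at least two intervening
  decoys or drop one marker, so a neighbor scan has an exact expected
  yield.
* **Identity-structured families** (`make_family_with_identity()`) give
  blocks with a target mean pairwise identity. Each member mutates each
  site of a block ancestor with probability `m`, chosen by solving
  `(1-m)^2 + m^2/19 = target`; unrelated blocks sit near the ~5%
  background.
* **Progress curves** integrate
  `dP/dt = kcat E0 (S0-P) / (KM (1+P/Ki) + (S0-P))` (plain
  Michaelis–Menten when `Ki` is absent) and add i.i.d. Gaussian noise on
  the signal — the simplest model matching photometric assays.

What the generator does not emulate: codon-level processes, heterotachy,
site-specific rate or frequency profiles, alignment errors from real
aligners, database contamination, or enzyme hysteresis/lag phases. Passing
tests therefore certify the algorithms under model-true conditions, not
robustness to real-data violations of those models.

## Trees, MCMC and diagnostics

Starting trees are neighbor joining (negative branches clamped to zero) on
maximum-likelihood pairwise distances. The ML search alternates
per-branch Brent optimization (round-robin sweeps until the log-likelihood
gain per sweep drops below `tol`) with best-improving nearest-neighbor
interchanges; ties go to the first candidate in a fixed enumeration order
for determinism, and the likelihood is non-decreasing by construction.

The Bayesian sampler is Metropolis–Hastings over topology (random NNI,
uniform prior), branch lengths (multiplier proposals, exponential(10)
prior), and optionally the gamma shape (sliding window). Defaults mirror
the shape of a typical published analysis — four chains and 10% burnin —
at desk scale (2000 samples by default; the bundled demo uses a few
hundred). Convergence is judged exactly as the field does: `maxdiff()`,
the maximum across chain pairs of the absolute difference in bipartition
frequencies over all observed nontrivial splits (whether a frequency floor
should exclude rare splits is ambiguous in common usage; all observed
splits are used here), and `ess()`, the autocorrelation-adjusted effective
sample size with the initial-positive-sequence truncation, capped at the
trace length. `consensus_with_support()` builds the majority-rule
consensus greedily extended with compatible splits, supports being pooled
post-burnin frequencies.

Outgroup rooting places the root on the branch separating a monophyletic
outgroup and splits that branch 50:50 — the placement along the branch is
not identifiable under a reversible model, so an explicit convention is
required. For the same reason the two edges incident to the root of a
rooted tree are only jointly identifiable, and branch-length recovery is
assessed on the unrooted topology.

## Ancestral reconstruction

`marginal_posteriors()` computes, per node and column, the posterior over
residues by combining the upward (subtree) partials with downward partials
from the rest of the tree, the root prior being the model's equilibrium.
Marginal (per-node) rather than joint reconstruction is primary, matching
the standard most-likely-sequence export of ancestral reconstruction
tools. Indels are reconstructed on a binary presence/absence recoding
under a reversible two-state CTMC with equal equilibrium frequencies and a
single `gain_loss_rate` (default 1.0 on the branch-length scale; it is a
stand-in convention, not an estimate). The most likely sequence at a node
emits the argmax residue wherever the presence posterior is at least 0.5
(presence-favoring at exactly 0.5) and a gap otherwise; argmax ties break
alphabetically. The MRCA of a single-leaf clade is defined as the leaf
itself; callers wanting its parent must ask explicitly.

At a total root-to-tip divergence of 0.5 substitutions per site the
reconstruction recovers ancestral sequences at well above 90% identity
(measured across all internal nodes over replicate simulations in the test
suite), and accuracy declines monotonically with divergence.

## Similarity networks and motifs

The SSN stage filters sequences to a length window (inclusive bounds;
230–260 for the real superfamily, configurable), collapses near-identical
sequences greedily (longest first, join on identity strictly above the
threshold over the shorter sequence; 100%-identical duplicates always
merge), and scores all representative pairs by Smith–Waterman local
alignment converted to bit scores and E-values with Karlin–Altschul
statistics (`E = m n 2^(-S')`, published gapped BLOSUM62 parameters
lambda = 0.267, K = 0.041, gaps 11/1, pairwise search space `m n`).
Absolute E-values will differ from a database BLAST — no composition-based
statistics or finite-size correction — so the tests assert orders of
magnitude and monotonicity, never engine-equality. Components come from
union-find on the edge list; per-component identity statistics use
global-alignment identity over aligned columns.

Motif analysis maps structure-anchored residue positions through the
alignment (column of the k-th non-gap reference character), extracts
8-residue motifs, and matches them against the PriA-typical
D-R-E-D-R-G-W-D reference either strictly or with residue equivalence
classes (`basic = {R, K}` by default, since a basic residue at the
arginine slot preserves function). Only some slot positions are anchored
by published structure numbering, so the full position list is user
configuration rather than a hard-coded constant. Sequence logos use
`R = log2(20) - H` with gaps excluded from the frequency denominator and no
small-sample correction — intended cluster sizes are large, and the choice
is explicit.

## Kinetics

`integrated_mm_product()` evaluates the closed-form integrated
Michaelis–Menten solution
`P(t) = S0 - KM W((S0/KM) exp((S0 - kcat E0 t)/KM))` through a log-argument
Lambert-W solver (safeguarded Newton on `w + log w = y`), which cannot
overflow for large `S0/KM`; it agrees with direct ODE integration to
better than 0.1% everywhere tested. Initial-rate fits
(`fit_initial_rates()`) fall back to the linear regime — reporting only
`kcat/KM` with a flag — when saturation is not reached. Progress-curve
fits (`fit_progress_curves()`) are single global least-squares fits across
all curves on log-scale parameters with five log-spaced multi-starts;
standard errors come from the Jacobian at the optimum, and an
ill-conditioned Jacobian flags the fit as non-identifiable instead of
failing silently. Product inhibition is modeled as competitive (the
inhibitor term scales KM) — the standard choice for this product class —
with an uncompetitive variant available behind a flag since the original
software's exact form is not documented. Fitting entire progress curves is
also the right tool when an enzyme shows hysteresis; no explicit
activation-lag parameter is fitted. Catalytic efficiencies are reported to
2 significant figures, the table convention.

`rank_concordance()` computes the Spearman correlation (midranks for ties)
between in vitro catalytic efficiencies and in vivo complementation times;
on the bundled published tables the ancestral TrpF efficiencies and
TrpF-deletion complementation times are perfectly anti-concordant
(rho = -1).

## Numerical choices and degenerate inputs

* Per-column rescaling with accumulated log factors prevents likelihood
  underflow on any tree size used here.
* `P(t)` entries are clamped at 0 against round-off negatives; rows sum to
  1 within 1e-10.
* Zero-length branches are valid (identity transition); negative lengths
  are errors. The Yule sampler floors coincident event times at 1e-8.
* Zero-variance MCMC traces return ESS = N with a warning rather than
  dividing by zero.
* A column gapped in both sequences contributes to no percent-identity
  denominator; a zero denominator is an explicit error.
* All-gap logo columns return NA rather than 0 bits.

## Problem sizes

The bundled demo and the test suite run at desk scale by choice: families
of 6–16 taxa and 100–1000 columns, MCMC runs of a few hundred samples per
chain, kinetics with five substrate concentrations and 50-replicate noise
studies. These sizes are where the oracles (enumeration, closed forms,
independent implementations) are exact or cheap; every algorithm scales to
the real superfamily sizes in the obvious way, only more slowly.

## Known limitations

Alignment is progressive with a k-mer/UPGMA guide tree — adequate at these
divergences, but without iterative refinement or consistency scoring.
Tree search is NNI-only (no SPR/TBR), and there is no model selection or
partitioned modeling across the concatenated gene segments. The sampler's
fixed empirical exchangeabilities cannot capture site-specific frequency
classes. E-values are calibrated analytically, not empirically. None of
the wet-lab-facing quantities (expression, purification, complementation)
are modeled; printed tables of such measurements are treated as inputs.
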