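# hisatrace

Tools for tracing bi-functional enzymes — the HisA/PriA isomerase
superfamily of histidine and tryptophan biosynthesis — across deep
evolutionary time. HisA (ProFAR isomerase) and TrpF (PRA isomerase)
catalyze analogous sugar isomerizations; in Actinobacteria a single
bi-functional HisA homolog, PriA, does both jobs. Deciding whether such
bi-functionality is a recent innovation or an ancient trait preserved for
billions of years takes a chain of very different computations, and this
package provides all of them as composable, tested R functions:

* **Sequence similarity networks** — length filtering, greedy >95%-identity
  representative collapsing, all-by-all Smith–Waterman edges scored with
  Karlin–Altschul statistics (`E = m·n·2^{-S'}`, bit score
  `S' = (λS − ln K)/ln 2`), connected components and per-cluster identity
  statistics.
* **Operon screening** — scanning gene tables (GFF3 or TSV) for species
  where *hisA*, *hisF* and *hisH* are gene neighbors, and species-wise
  concatenation (HisF + HisA + HisH) with exact partition bookkeeping.
* **Alignment** — progressive profile–profile alignment with affine gaps on
  a 3-mer/UPGMA guide tree, and trimming of columns with more than 50% gaps.
* **Phylogenetics** — Felsenstein-pruning likelihoods under JTT/WAG
  (optional discrete gamma), ML distances + neighbor joining, NNI maximum
  likelihood search, Bayesian MCMC over topologies and branch lengths, the
  `maxdiff` split-frequency discrepancy, autocorrelation-corrected effective
  sample sizes, majority-rule consensus trees with supports, and outgroup
  rooting.
* **Ancestral sequence reconstruction** — marginal per-column residue
  posteriors by the up/down pruning passes, two-state indel reconstruction,
  and most-likely ancestor extraction at any clade's MRCA.
* **Active-site motifs** — mapping structure-anchored positions through an
  alignment, matching against the PriA-typical D-R-E-D-R-G-W-D motif
  (strict or with residue equivalence classes such as basic = {R, K}), and
  sequence logos (`R = log2 20 − H` bits).
* **Enzyme kinetics** — Michaelis–Menten fits from initial rates and from
  entire progress curves via the integrated rate equation
  `P(t) = S0 − KM·W((S0/KM)·e^{(S0 − kcat·E0·t)/KM})` (Lambert W, with an
  overflow-safe log-argument solver), optional competitive product
  inhibition, catalytic efficiencies kcat/KM, and Spearman rank concordance
  between in vitro efficiencies and in vivo complementation times.
* **Synthetic data with known ground truth** — protein families evolved
  along known trees (true ancestors retained), synthetic genomes with a
  controlled fraction of marker-gene neighborhoods, homolog families with
  prescribed identity structure, and noisy progress curves. Every
  downstream stage is testable end to end without touching a database.

`run_pipeline()` chains the stages (simulate → scan → concatenate →
align/trim → tree + diagnostics → ASR → SSN → motifs → kinetics) from one
validated config and writes all artifacts plus a JSON manifest. A bundled
demo config (`inst/extdata/demo_config.yaml`) runs end to end in about a
minute on one CPU.

## Worked example

Simulate a family along a known tree, reconstruct its root, and fit kinetic
constants from noisy progress curves:

```r
library(hisatrace)

tree <- sample_yule_tree(8, birth_rate = 1, seed = 7)
tree$edge.length <- tree$edge.length * 0.5 / max(ape::node.depth.edgelength(tree))
fam <- evolve_alignment(tree, root_length = 200, aa_model("JTT"), seed = 7)
fam
#> <simulated_family> 8 leaves, 200 columns, 7 true ancestors

rec  <- ancestral_reconstruction(fam$tree, fam$alignment)
root <- extract_ancestor(rec, tree$tip.label)
percent_identity(root$ml_sequence, fam$true_ancestors[["N1"]])
#> 78.5
```

At 0.5 substitutions/site root-to-tip the most-likely root sequence
recovers 78.5% of the true simulated root (the root is the hardest node;
averaged over all internal nodes, recovery at this divergence is ~94%).

```r
curves <- simulate_progress_curves(kcat = 0.9, KM = 28, E0 = 0.1,
                                   S0_list = c(10, 20, 40, 80, 160),
                                   noise_sd = 0.05, dt = 10, t_end = 3000,
                                   seed = 7)
fit <- fit_progress_curves(curves, model = "plain")
tidy(fit)
#> # A tibble: 2 × 3
#>   term  estimate std.error
#>   <chr>    <dbl>     <dbl>
#> 1 kcat     0.900  0.000117
#> 2 KM      28.0    0.0127
glance(fit)[, c("kcat", "KM", "kcat_over_KM")]
#> # A tibble: 1 × 3
#>    kcat    KM kcat_over_KM
#>   <dbl> <dbl>        <dbl>
#> 1 0.900  28.0       32137.
```

The global fit across five substrate concentrations recovers the generating
constants (kcat 0.9 s⁻¹, KM 28 µM, kcat/KM = 3.2·10⁴ M⁻¹s⁻¹) from 5%-noise
curves. Finally, the bundled published tables connect kinetics to
physiology:

```r
kin <- extant_kinetics()
eff <- setNames(kin$eff_Ms[kin$reaction == "TrpF" & grepl("^CA-", kin$enzyme)],
                kin$enzyme[kin$reaction == "TrpF" & grepl("^CA-", kin$enzyme)])
tms <- complementation_times()
rank_concordance(eff, setNames(tms$delta_trpF_h, tms$enzyme))
#> -1
```

The TrpF catalytic efficiencies of the three reconstructed ancestors are
perfectly anti-concordant with the time their hosts need to complement a
*trpF* deletion — faster enzyme, faster rescue.

See `vignettes/tracing-bifunctionality.Rmd` for the models, parameter
conventions and design decisions.

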