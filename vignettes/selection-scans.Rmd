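---
title: "Selection scans with altiscan: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection scans with altiscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altiscan)
```

# The scientific problem

Lineages that independently colonise high altitude offer natural replicates
for asking how genomes respond to hypoxia, cold and ultraviolet stress.
`altiscan` implements the two complementary scans used in comparative
transcriptome studies of such systems:

1. **Deep-time scans** on codon alignments of orthologs across species: the
   nonsynonymous/synonymous rate ratio \(\omega = d_N/d_S\) measures the
   strength and direction of protein-level selection accumulated since
   lineages diverged. Branch models ask whether a focal (high-altitude)
   branch evolved faster overall; branch-site models ask whether a subset of
   codons on that branch experienced positive selection (\(\omega > 1\)).
2. **Shallow-time scans** on SNP allele frequencies across populations along
   altitudinal transects: loci whose differentiation (\(F_{ST}\)) is
   unusually high suggest local (diversifying) selection, unusually low
   differentiation suggests balancing selection.

Everything in between — ortholog inference, alignment quality control, SNP
calling, enrichment statistics — is included so the whole analysis is a
single reproducible pipeline. Synthetic-data generators with known truth
stand in for sequencing data, which makes every stage testable offline.

# Codon models

## The substitution model

All likelihood machinery uses the Goldman–Yang codon model over the 61 sense
codons of the universal code. The instantaneous rate from codon \(x\) to
\(y\) is zero if they differ at more than one position and otherwise

\[ q_{xy} \propto \pi_y \,\kappa^{[\mathrm{transition}]}\,
   \omega^{[\mathrm{nonsynonymous}]} , \]

with stationary codon frequencies \(\pi\), transition/transversion ratio
\(\kappa\), and \(\omega\) the nonsynonymous/synonymous rate ratio. A single
matrix is scaled to one expected substitution per codon per unit branch
length, so branch lengths are in substitutions per codon
(`build_rate_matrix()`). Codon frequencies default to the F3×4 estimate from
the alignment (position-specific nucleotide frequencies), a common default
when the frequency model is not otherwise specified; any 61-vector can be
supplied instead.

Likelihoods are computed by Felsenstein pruning over the 61 states in a
compiled kernel, with spectral decomposition of the (reversible) rate matrix
for transition probabilities and per-pattern scaling for deep trees. Gaps,
ambiguities and stop codons are treated as missing data at the affected
tips. The pruning result is tested against brute-force enumeration over
internal-node codon assignments on small trees.

## Branch and branch-site models

`fit_m0()` fits one \(\omega\) for the whole tree; `fit_branch()` fits one
\(\omega\) per branch class (by default, per branch). `fit_branch_site()`
fits model A: four site classes in proportions
\(\{p_0, p_1, p_{2a}, p_{2b}\}\) where class 0 sites evolve at
\(\omega_0 < 1\) everywhere, class 1 sites neutrally, and class 2 sites take
\(\omega_2\) on the designated foreground branch. The null fixes
\(\omega_2 = 1\); the likelihood ratio statistic is referred to
\(\chi^2_1\). Because the true null distribution at the boundary is a 50:50
mixture of \(\chi^2_1\) and a point mass at zero, the \(\chi^2_1\) reference
is conservative; we prefer the conservative choice and report BH q-values
across genes alongside the raw `p < 0.05` rule used to nominate putatively
selected genes.

**Mixture scaling.** Within a site-class mixture the class-specific rate
matrices on a branch share a *common* scale factor (the class-weighted mean
rate). This is the convention CODEML uses and it matters: normalising each
class separately would force positively selected sites to have the same
total substitution rate as purifying sites, erasing most of the elevated
nonsynonymous signal the test looks for. The simulator uses the identical
convention, so parameter recovery is internally consistent.

## Optimization

Fits use coordinate-wise bounded Brent searches (on log scale for rates and
branch lengths) with per-parameter windows that shrink to the previous step
size, under bounds \(\omega \in [10^{-4}, 999]\), \(\kappa \in [0.1, 99]\),
branch lengths \(\le 50\). `fit_m0()`/`fit_branch()` use two starts
(\(\omega \in \{0.5, 2\}\)) and iterate to a log-likelihood tolerance of
\(10^{-6}\). For `fit_branch_site()` the alternative model is *anchored at
the optimized null* (the models coincide at \(\omega_2 = 1\)), preceded by a
coarse one-ratio warm start and a small \(\omega_2\) grid. Monotone ascent
from that anchor guarantees
\(\ln L_{\mathrm{alt}} \ge \ln L_{\mathrm{null}}\), and because both fits
share the anchor, residual optimizer error largely cancels in the LRT; we
therefore run the branch-site coordinate ascent to a \(10^{-4}\) tolerance,
which halves cost with no measurable effect on test calibration (null
rejection stays below the nominal 5%).

## What the codon simulator does and does not emulate

`simulate_codon_alignment()` draws the root from \(\pi\) and evolves sites
independently down the tree; site classes are i.i.d. across codons and true
class labels are returned for power/type-I bookkeeping. It produces no
gaps, no alignment error, no rate variation beyond the site classes, and no
codon usage structure beyond \(\pi\). Passing tests therefore demonstrate
correctness of the inference machinery under the model's own assumptions —
not robustness to misalignment or model violation, which real
transcriptome data add on top.

# Alignment quality control

Orthologs come from best reciprocal hits (`best_reciprocal_hits()`): `a`
and `b` pair iff each is the other's top-scoring cross-species match with
both e-values at or below \(10^{-10}\). "Best" means highest bit score,
ties broken by lower e-value then lexicographic subject id; tie-broken
pairs are flagged because the underlying search gives no guidance. Hit
tables can be imported from BLAST tabular files or, for fixture-scale data,
computed with the built-in six-frame Smith–Waterman search
(`translated_hit_table()`; BLOSUM62, affine gaps 11/1, Karlin–Altschul
e-values with gapped constants).

Codon alignments are then filtered in a fixed order:

* `validate_codon_alignment()` — internal (non-terminal) stop codons, and
  nucleotide length below 200;
* `trim_alignment()` — a transparent column rule replaces block-based
  trimmers: any codon column whose gap-or-N fraction exceeds a threshold
  (default 0) is removed. The rule is deliberately simple so that it is
  exactly testable (idempotence, order preservation);
* `saturation_filter()` — pairwise NG86 \(d_S\) (counting estimator with
  Jukes–Cantor correction) flags a gene when any pair is undefined
  (synonymous difference proportion \(\ge 3/4\)) or exceeds a cap
  (default 3). Because no specific published test is named for this step,
  the cap is a documented, configurable operationalization. Note a ceiling
  effect: at extreme divergence the counting estimator itself saturates, so
  finite estimates bunch just below ~3.5 and roughly a quarter of fully
  saturated pairs escape the default cap; the infinite-\(d_S\) rule catches
  the rest. NG86 site counting treats mutations to stop codons as
  nonsynonymous and averages multi-step differences over mutation pathways
  that avoid stops.

# Rate comparisons and category statistics

`bootstrap_branch_rates()` resamples codon columns of the concatenated
alignment (the codon column is the resampling unit so the codon model stays
well-defined), refits the branch model per replicate, and
`binomial_rate_test()` compares two branches by counting replicates where
one exceeds the other (ties as half-successes; exact two-sided binomial
against 1/2). Replicates are *paired* — the two branches are compared
within the same resample — which maximizes power. A caveat documented here
because it is easy to miss: paired replicates share the original dataset,
so under equal true rates the per-dataset success fraction is approximately
uniform rather than concentrated at 1/2, and the procedure rejects more
often than its nominal level. It should be read as a descriptive
consistency check on bootstrap distributions, not a calibrated test; the
package reports it because it is the field's customary summary.

`category_rates()` compares each annotation category's mean per-gene
\(\omega\) (branch-model estimate on the focal branch) against means of
random same-size gene sets from the universe (upper-tail resampling p,
BH-FDR across categories, categories under 5 genes skipped).
`enrichment_test()` is the standard hypergeometric over-representation test
with BH q-values.

# The F_ST outlier scan

`bayescan_scan()` implements the hierarchical Bayesian outlier model: for
locus \(i\) in population \(j\),

\[ \mathrm{logit}\, F_{ST}^{(ij)} = \alpha_i + \beta_j , \qquad
   \tilde p_{ij} \sim \mathrm{Beta}\!\big(p_i \theta_{ij},
   (1-p_i)\theta_{ij}\big), \quad \theta_{ij} = 1/F_{ST}^{(ij)} - 1 , \]

with binomial sampling of allele counts, uniform priors on ancestral
frequencies \(p_i\), \(\beta_j \sim N(-1, 1.8)\) and, when included,
\(\alpha_i \sim N(0, 1)\). A reversible-jump move toggles each \(\alpha_i\)
against prior odds 10:1 for neutrality (the scan tool's published
defaults; the source study names the tool without run settings). The
posterior inclusion probability \(P_i\) yields q-values as the cumulative
mean of \(1 - P\) down the ranked loci; loci with \(q < 0.05\) are
classified diversifying or balancing by the sign of the posterior mean
\(\alpha\). Proposal scales are tuned in pilot rounds to 25–45%
acceptance. The sampler was validated against dense-grid numerical
posteriors (inclusion probabilities and \(\alpha\) means agree to Monte
Carlo error), and identical seeds reproduce identical summaries.

Default run control follows the published tool defaults (20 pilot rounds ×
2000, 50,000 burn-in, 5,000 samples at thinning 10); the bundled tests and
pipeline use short chains (5,000 burn-in, 2,000 samples) which the
grid-validation shows are already well converged at these data sizes.

**Power at transect scale.** With 5 populations of 20 diploids, a planted
effect of \(|\alpha| = 2\) gives Bayes factors of roughly 15–500 depending
on the ancestral frequency draw, so only the better-placed planted loci
clear \(q < 0.05\); the *sign* of the posterior \(\alpha\) is nevertheless
recovered for >90% of planted loci. This is a property of the model and
data sizes (confirmed against exact numerical posteriors), and it matches
the design logic of transect studies: consistency across independent
comparisons (`transect_consistency()`), not single-scan significance,
carries the inference.

The island-model generator (`simulate_allele_counts()`) is the exact
generative counterpart of this likelihood. Its ancestral-frequency prior
defaults to Beta(2, 2): the loci a genotyping panel interrogates are
ascertained as SNPs beforehand, so mid-range frequencies are realistic;
Beta(1, 1) is available for unascertained loci. Default \(\beta = -1\)
(neutral \(F_{ST} \approx 0.27\)) matches the prior mean; studies with much
deeper background differentiation can raise \(\beta\).

Companion QC: `hwe_exact()` (biallelic exact conditional test, validated by
exhaustive enumeration), `ld_test()` (Monte-Carlo exact probability test on
the two-locus genotype table), and `wc_fst()` (Weir–Cockerham variance
components from allele counts; global value is the ratio of summed
components).

# SNP tagging

`call_snps()` applies the strict coverage rule: a site is a SNP only if at
least two alleles are observed and the rarer of the top two has coverage
strictly greater than 20 (so exactly 20 fails). Indel evidence is not
considered. `select_tag_snps()` keeps up to two SNPs per gene ranked by
rare-allele coverage with positional tie-breaks — the ranking rule is this
package's choice, as the source analyses report tag counts without stating
one.

# The pipeline and the bundled synthetic study

`run_pipeline()` chains the stages (orthology → filtering → branch-site
scan → rates/enrichment → SNP tagging → outlier scans global and
per-transect) and writes every stage table with a provenance header
(package version, configuration hash, seed); identical configuration and
seed give byte-identical outputs. The bundled synthetic study uses 10
genes of 150 codons on a five-taxon tree (two high/low species pairs plus a
deep outgroup) with 2 planted positively selected genes, and a 60-locus,
5-population SNP panel with 3 planted diversifying loci — sized so the full
run takes about a minute and a half while still exercising every stage.
Test problem sizes throughout (e.g. 200 null genes at 200 codons for LRT
calibration, 100-locus panels for scan calibration) were chosen as the
smallest at which the calibration quantities are statistically meaningful.

# Numerical choices and degenerate inputs

* Eigendecomposition of the symmetrized rate matrix gives transition
  probabilities; tiny negative entries are clamped at zero. Zero codon
  frequencies get a pseudo-frequency with a warning.
* Zero branch lengths, all-gap columns, duplicated columns, monomorphic
  loci and empty inputs are all defined behaviour covered by tests (no
  change, no effect, exact doubling, exclusion-with-count, and
  empty-output-with-warning respectively).
* Alignments with fewer than two variable codon columns yield a flagged
  low-information LRT rather than an error; non-converged optimizations are
  flagged, not thrown.
* The binomial test reports exact tail sums; values below double precision
  appear as 0 and should be read as "< 1e-300".

# Known limitations

* Site classes are i.i.d. and there is no among-site rate variation beyond
  model A's classes; no Bayes empirical Bayes identification of selected
  sites.
* The built-in translated search is for fixture-scale data; genome-scale
  searches should import external BLAST tables.
* The outlier model is biallelic beta-binomial (no multiallelic
  Dirichlet-multinomial, no hierarchical regional structure); isolation by
  distance is addressed by the transect design rather than modelled.
* The paired bootstrap binomial comparison is anticonservative by
  construction (above); treat small p-values as descriptive.
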