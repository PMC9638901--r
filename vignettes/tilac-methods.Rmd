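---
title: "tilac: model, simulator and numerical design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tilac: model, simulator and numerical design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the mixture model and its assumptions, the tunable parameters and why their
defaults are what they are, what the simulator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## 1. The measurement and the estimand

Two RNA populations are labelled with different nucleoside analogues —
4-thiouridine (s4U) and 6-thioguanosine (s6G) — pooled, and sequenced as a
single library. Recoding chemistry turns incorporated s4U into a base read
as C (T-to-C mismatches against the reference) and s6G into a base read as
A (G-to-A mismatches). Each sequencing read therefore carries two mutation
counts, one per channel, and the per-gene mixture of labelled and
unlabelled reads in each channel encodes how much RNA each population
contributed.

Label incorporation is not symmetric between the two analogues, so every
experiment combines two reciprocal labelling schemes: *forward*
(experimental condition s4U, control s6G) and *reverse* (the swap), plus
*unlabelled* controls carrying neither analogue. The estimand for gene *g*
is the internally normalized abundance ratio

$$\mathrm{TILAC\ ratio}_g = \theta_{exp,g} / \theta_{cntl,g},$$

where $\theta_{c,g}$ is the fraction of gene *g*'s reads carrying condition
*c*'s label. Because both conditions travel through the same library, the
ratio needs no spike-ins or size factors, and genuinely global changes
(e.g. transcription shutdown) remain visible.

## 2. The probability model

Reads are aggregated into groups sharing (gene, sample, channel, mutations
per read); group counts are the sufficient statistics. For a labelled
sample *s* and channel $m \in \{\mathrm{TC}, \mathrm{GA}\}$ the per-read
count is a two-component Poisson mixture

$$f(y_m) = I_s\,\theta_{c,g}\,\mathrm{Pois}(y_m \mid \lambda_{l,m})
         + (1 - I_s\,\theta_{c,g})\,\mathrm{Pois}(y_m \mid \lambda_{u,m}),$$

with $I_s = 0$ for unlabelled controls (pure background). The channel-to-
condition routing implements the reciprocal design: in a forward sample the
T-to-C channel informs $\theta_{exp}$ and G-to-A informs $\theta_{cntl}$; a
reverse sample swaps them.

Model assumptions worth stating explicitly:

* **Rates are global.** $\lambda_{u,m}$ (background, sequencing error) and
  $\lambda_{l,m} = \lambda_{u,m} + TL_m$ (labelled) are shared across all
  genes. There is no gene-specific incorporation rate and no
  overdispersion.
* **Rates are per read, not per site.** The Poisson rate does not condition
  on the read's U/G content. `fitTilac` follows this exactly; per-group
  mean site counts are retained in the count table so a site-exposure
  variant could be built, but none is offered by default — fidelity to the
  simple per-read likelihood comes first.
* **Channels are independent factors.** Both channels of every read enter
  the likelihood, each routed to its own condition. This is what makes an
  unlabelled read informative twice over (background in both channels).
* **Replicates share $\theta$.** All forward and reverse replicates of a
  comparison inform one $(\theta_{exp,g}, \theta_{cntl,g})$ pair; there is
  no replicate-level hierarchy.

Priors (all weakly informative): $\log \lambda_{u,m} \sim N(-2, 2)$ —
centred at ~0.14 mutations per read, generous for sequencing error;
$TL_m \sim \mathrm{Exponential}(\mathrm{rate} = 0.5)$ — mean 2, the scale
of per-read counts in well-labelled reads (the rate-0.5 reading of the
exponential is deliberate: with ~50 covered U sites and a ~5% per-base
rate, labelled reads average ~2.5 mutations); additive $TL_m \ge 0$
enforces $\lambda_l \ge \lambda_u$; and
$\mathrm{logit}(\theta) \sim N(0, 1.5)$, nearly flat on (0,1) with light
shrinkage from the boundaries. The background is anchored by unlabelled
controls; `fitTilac` refuses to run without one unless $\lambda_u$ (or the
whole rate set) is fixed explicitly.

## 3. Testing

The posterior mean and sd of $\log_2(\theta_{exp}/\theta_{cntl})$ feed a
composite-null test of $|\mu| \le \mu_{\mathrm{cutoff}}$ (default 0.5 on
the log2 scale): under the normal approximation to the posterior,

$$p = S\!\left(\frac{|m| - c}{s}\right) + S\!\left(\frac{|m| + c}{s}\right),$$

the two-boundary tail sum used by threshold-based fold-change tests. At
$m = 0$ the two tails are complementary and $p = 1$ exactly; the test is
evaluated at the boundary of the null set and is conservative inside it.
Benjamini–Hochberg correction is applied across the tested family at
$\alpha = 0.05$. Genes failing the convergence gates are excluded from the
family (and reported), not assigned $p = 1$: an unconverged posterior
summary is not evidence, and inflating the family would distort the
correction for everyone else. The test consumes the (mean, sd) summary;
draws are retained in the fit object so a draw-based variant can be
compared if wanted.

## 4. Sampling and its cross-check

The joint posterior over 4 global parameters and $2G$ gene fractions is
sampled with adaptive Metropolis-within-Gibbs:

* global coordinates (log $\lambda_u$, log $TL$ per channel) are updated
  one at a time with random-walk proposals; each touches a single channel,
  so only that channel's likelihood rows are recomputed;
* gene fractions are conditionally independent given the global rates, so
  all genes' logit-$\theta$ updates are proposed, evaluated and
  accepted/rejected simultaneously in vectorized form — one sweep costs a
  handful of whole-table vector operations regardless of gene count;
* proposal scales adapt by Robbins–Monro during warm-up only (targets 0.35
  global, 0.44 per-gene), then freeze, keeping the kept draws a valid
  Markov chain.

Defaults: 4 chains, 1000 warm-up + 1000 kept sweeps, run sequentially from
a single seed, so fits are exactly reproducible. Convergence is gated per
gene at split-$\hat{R} \le 1.01$ (max over $\theta_{exp}$, $\theta_{cntl}$
and the log2 ratio) and effective sample size $\ge 100$ for the log2
ratio; failures are flagged, never silently accepted.

Numerical floors and degenerate inputs: $\theta$ lives on the logit scale
and is clamped to $(10^{-6}, 1 - 10^{-6})$; all mixture terms use
log-space summation; a gene with no data in one condition simply keeps its
prior for that fraction; an empty count table is an error; ties in the
deterministic count-table sort are impossible because the sort key is the
full grouping key.

The sampler is validated against an independent path: with the global
rates fixed, the likelihood factorizes over the two conditions and the
exact posterior is computable by 1-D quadrature per condition on a logit
grid (a product 2-D quadrature). `gridPosterior` refines the grid until
the posterior mean of the log2 ratio moves by less than `tol` (default
1e-4) between doublings and errors out if resolution is exhausted. The
test suite checks sampler-vs-quadrature agreement within 3 Monte-Carlo
standard errors on 20 randomized single-gene instances.

## 5. The simulator

`simulateReads` implements the generative model the calibration studies
assume: per transcript, $\mathrm{logit}(\theta_{cntl})$ is drawn Normal
around $\mathrm{logit}(1/(1 + \mathrm{ratio}))$ with sd 0.5 and
$\theta_{exp} = \mathrm{ratio} \cdot \theta_{cntl}$ (pairs summing above
one are rescaled to $1 - 10^{-6}$, preserving the ratio — the source
description of this draw admits more than one reading, and this one keeps
the requested ratio exact while placing the pair near the simplex);
per sample, reads are assigned multinomially to experimental-labelled,
control-labelled and unlabelled pools; each read's U/G content is
Multinomial(200; 0.25, 0.25); and mutation counts are Binomial per covered
site — 0.05/0.001 per U (labelled/background T-to-C) and 0.02/0.004 per G
(G-to-A). Read counts are fixed or Poisson around per-transcript means
(template mode); a packaged *synthetic* template mimics the shape of a
transcription-inhibition dataset (long-tailed counts, predominantly
negative log2 ratios) without containing any real data. Three regulation
regimes derive from a template: down (as is), up (log-ratios negated),
symmetric (mean log-ratio subtracted).

Two deliberate properties: mutation counts are generated **binomially**
although the model fits a Poisson — a mild, intentional misspecification
matching how such data arise; and `emitSyntheticSam` can materialize any
simulated tally as a SAM/FASTA/GTF fixture whose re-tallying reproduces
the tallies bit-for-bit, which is how the alignment front end is tested
without shipping binary data.

What the simulator does **not** emulate: PCR duplicates, quality-score
profiles, alignment error, splicing structure, coverage biases within
transcripts, gene-to-gene rate variation, or dropout. Passing calibration
here therefore demonstrates correctness of the inference given the model's
data-generating assumptions, not robustness to every artifact of real
libraries.

## 6. Tallying choices

The alignment front end keeps FLAGs {83, 163, 99, 147} with MAPQ ≥ 2,
assigns read templates to genes by span overlap (single-gene hits only;
two or more gene spans → ambiguous, dropped), and classifies exonic vs
intronic by whether all aligned blocks sit inside the gene's exon union.
Mismatch counting is strand-aware (for minus-strand genes, reference A→G
plays the role of T-to-C and C→T of G-to-A), skips insertions and soft
clips, enforces a base-quality floor (default Q20 — the convention in
mutation-counting pipelines; the floor applies to denominator and
numerator alike so rates stay unbiased), removes positions listed in a
VCF-derived SNP mask from both numerator and denominator, and counts
mate-overlapping positions once (first mate wins). Coordinates are 1-based
inside SAM/GTF/VCF parsing, as those formats define; BED blocks are
converted on import by rtracklayer. Coverage filtering keeps genes with at
least 200 reads in at least two samples; the boundary is inclusive
(exactly 200 qualifies) and the same inclusive rule is used everywhere a
read-count threshold appears, including raw mutation-rate summaries.
Exonic and intronic reads are pooled for model fitting by default, with
the feature class kept on every tally so a stratified analysis remains a
one-line filter.

## 7. Calibration scale

The shipped calibration uses desk-scale problem sizes chosen to exercise
the method at the depths where its guarantees are claimed: ~600
transcripts at 500 reads for FDR control (80% nulls, 20% alternatives at
|log2 ratio| ≥ 2), 200 transcripts for rate recovery, 50 transcripts per
ratio across the grid 0.01–100 for dynamic range (regression slope
assessed over 0.1–100, the depth-supported range; the most extreme ratios
show visible prior shrinkage below ~200 reads), 20 single-gene instances
for the quadrature cross-check. Larger sweeps are available through
`accuracySweep` by raising its cell sizes.

## 8. Known limitations

* No hierarchical shrinkage across genes and no dispersion parameter: a
  gene whose true incorporation deviates from the global rates will be
  mis-calibrated, not flagged.
* The normal approximation behind the composite-null p-value can be poor
  for genes whose $\theta$ posteriors pile against a boundary (very
  extreme ratios at low depth).
* Two conditions only; multi-condition designs require separate pairwise
  fits.
* The tallying stage assumes a single genome alignment plus annotation; it
  does not reconcile separate transcriptome alignments, call SNPs, or
  deduplicate reads — those remain upstream concerns.
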