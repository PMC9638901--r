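# tilac

Internally normalized differential RNA abundance from dual metabolic
labelling RNA-seq.

## The problem

Standard RNA-seq compares libraries that were prepared and sequenced
separately, so global shifts in RNA levels (a transcription shutdown, a
stress response) are silently normalized away unless external spike-ins are
added. TILAC-style experiments avoid this by labelling the two RNA
populations metabolically — one sample with 4-thiouridine (s4U), the other
with 6-thioguanosine (s6G) — and pooling them into a **single** sequencing
library. Recoding chemistry converts the incorporated analogues so that
s4U-labelled reads carry excess T-to-C mismatches and s6G-labelled reads
carry excess G-to-A mismatches. The two populations are then deconvolved
computationally from the mutational content of each read, making the
comparison internally normalized: no spike-ins, no library-size factors.

Because the two labels incorporate with different efficiencies, experiments
use two reciprocal *combinations*: **forward** (experimental s4U + control
s6G) and **reverse** (experimental s6G + control s4U), plus **unlabelled**
controls that pin down the background mismatch rate from sequencing error.

## The model

Per-read mutation counts of channel *m* (T-to-C or G-to-A) in a labelled
sample are modelled as a two-component Poisson mixture,

    f(y_m) = I_s θ_c Pois(y_m | λ_l,m) + (1 − I_s θ_c) Pois(y_m | λ_u,m)

where θ_c is the gene's labelled fraction for condition *c* (experimental or
control, routed by the sample's combination and the channel), λ_u,m and
λ_l,m = λ_u,m + TL_m are global background and labelled per-read rates, and
I_s = 0 for unlabelled controls. Priors: log λ_u,m ~ Normal(−2, 2),
TL_m ~ Exponential(0.5), logit θ ~ Normal(0, 1.5). The quantity of interest
is the **TILAC ratio** θ_exp,g / θ_cntl,g, reported as its log2. The joint
posterior is sampled by adaptive Metropolis-within-Gibbs MCMC (4 chains,
1000 warm-up + 1000 kept draws, split-R̂ and ESS gates), and each gene's
log2 ratio is tested against the composite null |log2 ratio| ≤ 0.5 with a
TREAT-style two-boundary tail sum and Benjamini–Hochberg correction at
FDR 0.05. Genes need ≥ 200 reads in ≥ 2 samples to be analysed.

The package also contains the tallying front end (SAM + FASTA + GTF/BED +
optional VCF SNP mask → strand-aware per-read mismatch tallies) and the
full generative simulator (known truth, forward/reverse/unlabelled samples)
used for calibration.

## Worked example

Simulate six transcripts spanning true abundance ratios 0.25–4 under the
default generative settings (500 reads per transcript per sample; forward,
reverse and unlabelled samples), fit, and test:

```r
library(tilac)

design <- tilacDesign(c("fwd1", "rev1", "unl1"),
                      c("forward", "reverse", "unlabelled"))
sim <- simulateReads(c(0.25, 0.5, 1, 1, 2, 4), design,
                     reads_per_transcript = 500, seed = 42)
fit <- fitTilac(sim$counts, seed = 42)
fit
#> TilacFit: 6 genes; 4 chains x 1000 kept draws
#>   log2 TILAC ratio: median 0.060 [-1.861, 1.922]
#>   convergence: 6/6 genes pass (Rhat <= 1.01, ESS >= 100)

globalRates(fit)[, c("mut_type", "lambda_u_mean", "lambda_l_mean")]
#>   mut_type lambda_u_mean lambda_l_mean
#> 1       TC     0.0506571     2.5273018
#> 2       GA     0.1975670     0.9867805

tests <- callSignificance(fit, mu_cutoff = 0.5, alpha = 0.05)
testResults(tests)
#>   gene_id log2_ratio_mean log2_ratio_sd  p_value p_adjusted direction
#> 1      g1         -1.8600        0.1280 1.03e-26   3.08e-26      down
#> 2      g2         -0.9500        0.1130 3.49e-05   5.24e-05      down
#> 3      g3          0.0368        0.0873 1.00e+00   1.00e+00      none
#> 4      g4          0.0834        0.0877 1.00e+00   1.00e+00      none
#> 5      g5          1.1100        0.1020 1.09e-09   2.19e-09        up
#> 6      g6          1.9200        0.1330 5.94e-27   3.08e-26        up
```

The fitted global rates match the generative truth (background 0.05 and 0.2
mutations per read; labelled 2.5 and 1.0, i.e. per-base rates 0.05 and 0.02
over 50 covered sites). The posterior mean log2 ratios track the simulated
values (−2, −1, 0, 0, 1, 2); the two true nulls give p = 1 under the
composite null and everything else is called in the right direction.

Starting from alignments instead of a simulation:

```r
tallies <- tallyReads("reads.sam", "genome.fa", "genes.gtf",
                      sample_id = "fwd1", vcf_file = "snps.vcf")
counts  <- aggregateReads(tallies, design)
fit     <- fitTilac(filterLowCoverage(counts), seed = 1)
```

A thin command-line wrapper with subcommands `tally`, `simulate`, `fit`,
`test`, `report` and `pipeline` is installed at
`system.file("scripts", "tilac", package = "tilac")`.

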