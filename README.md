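# nucleocall

Nucleosome detection from strand-specific MNase-seq read starts.

## The problem

Sequencing MNase-digested mononucleosomes produces ~150 bp fragments whose
ends delimit histone-protected DNA. Single-end short reads taken from the
fragment 5' ends leave a three-part signature in the reference genome: a
peak of forward-strand read starts just upstream of the protected stretch,
a mirrored peak of reverse-strand starts just downstream, and a depletion
of starts over the protected DNA itself. Because adjacent nucleosomes sit
only 30–60 bp apart, strand-blind sliding-window peak callers blur them
into broad enriched regions. nucleocall is for researchers mapping
individual nucleosome positions (or nucleosome-sized protected particles)
at base-pair-scale resolution from modest-coverage single-end data.

## The method

Per strand, read 5' starts are counted at every base. A candidate
nucleosome starting at position *i* defines a forward support region
[*i−s*, *i−1*] (forward strand), a binding region [*i*, *i+b−1*] (both
strands) and a reverse support region [*i+b*, *i+b+s−1*] (reverse strand);
defaults *b* = 128, *s* = 17. Each region count is compared with a robust
local background estimate (2·*w*+1 = 2001 bp windows, capped between
adjacent non-overlapping windows by a Poisson quantile rule at
γ_bg = 0.9) using the two-sample Poisson likelihood-ratio statistic

W = 2{ x₀(ln x₀ − ln t₀) + x₁(ln x₁ − ln t₁) + (x₀+x₁)(ln[t₀+t₁] − ln[x₀+x₁]) },

asymptotically χ²₁ under equal rates. Support counts are cross-truncated
(a forward peak counts only as far as the reverse strand matches it, via a
Poisson quantile at γ_sup = 0.9). The nucleosome score
S(i) = S_fwd + S_bind + S_rev sums the signed square roots of the three
statistics — positive for enriched supports and a depleted binding region.
Significance comes from an empirical null N(μ̄, σ): μ̄ is the median valid
score and σ a truncated half-normal maximum-likelihood fit to the lower
percentile band of scores; q-values are Benjamini–Hochberg, and discrete
predictions are greedy score-ordered maxima at q ≤ 0.05 with a minimum
start separation. The package also ships the read simulator (stable /
phased / fuzzy / nucleosome-free chromatin with truth tables) and the
downstream analyses: dinucleotide periodicity around dyads, phasing at
TSS/TES anchors, adjacent-prediction distances, detection metrics,
total-correlation repeatability and Pareto-front parameter selection.

## Worked example

Simulate a 200 kb genome with the default chromatin mix, call nucleosomes,
and compare against the simulated truth:

```r
library(nucleocall)

p   <- sim_params(genome_length = 2e5, seed = 11, n_reads = 25000)
sim <- simulate_experiment(p)
res <- detect_nucleosomes(sim$reads, sim$genome)
res
#> nucleocall result: 561 predictions at FDR 0.05
#> empirical null: N(mu = -1.1620, sigma = 1.9390), tau = 5, n = 32737

head(res$predictions, 3)
#>   chrom start dyad    score            p            q
#> 1   sim    30   94 7.466408 4.295385e-06 0.0007695827
#> 2   sim    37  101 6.322820 5.666367e-05 0.0050154388
#> 3   sim    42  106 5.871871 1.430549e-04 0.0098169380

ev <- evaluate_predictions(res$predictions, sim$truth)
#> stable dyads detected: 23/23 (100.0%), median |offset| 1 bp, sd 1.5 bp
```

Each prediction row is one called nucleosome: `start` is the 0-based
binding-region start, `dyad = start + b/2` the inferred particle centre,
`score` the combined three-region statistic, and `p`/`q` its significance
under the empirical null. Overlapping predictions a few bp apart (as in
rows 1–3) reflect alternative particle positions supported by the reads —
real samples show the same pattern. The fitted null (μ̄ = −1.16, σ = 1.94)
describes the typical non-stable position; stable nucleosomes score far
into its upper tail, and here all 23 stable dyads are recovered with a
median offset of 1 bp.

A command-line front-end with `call`, `simulate`, `motif`, `phase` and
`sweep` subcommands is installed under `inst/scripts/nucleocall`:

```sh
Rscript inst/scripts/nucleocall simulate --out sim --length 1000000 --seed 1
Rscript inst/scripts/nucleocall call --reads sim.reads.bed \
    --sizes sim.sizes.tsv --out calls
```

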