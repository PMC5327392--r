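# coTFscan

Discovery of co-associated transcription factors from ChIP-seq peak
neighborhoods.

When two transcription factors (TFs) work together, the binding sites of
one cluster around the ChIP-seq peak points of the other, with a
peak-like (decaying) distance distribution. `coTFscan` turns that
signature into a motif ranking: given peak points for a ChIPed factor, a
genome FASTA, and a library of candidate motifs in TRANSFAC format, it
scores every motif on how sharply its binding strength drops with
distance from the peak points and ranks candidates by that score.

## The statistic

For each motif (a 4 × *l* frequency matrix Θ), every placement inside
±*m* bp windows around the peaks is scored with the log-odds PWM score
against a uniform background, min–max normalized to the binding score
*V* ∈ [0, 1]. Scores are pooled into *b* unsigned-distance bins and each
bin's scores sorted descending into the matrix *M*ₛ (*r* × *b*). The
motif's adjacency score combines:

* **first-order differences** f₁[i, j] = *M*ₛ[i, j] − *M*ₛ[i, j+1],
  summed over the top *t* rows per column, gamma-weighted toward
  peak-proximal bins, with *t* chosen per motif to maximize the sum:
  S₁(t) = Σⱼ g(j + ½ | c, γ) Σ_{i≤t} f₁[i, j];
* **second-order differences** f₂[i, j] = f₁[i, j] / maxᵢ |f₁[i, j]|,
  each bin pair contributing a bounded, composition-robust vote
  S₂ = Σⱼ (σ(zⱼ) − ½) with zⱼ = Σᵢ f₂[i, j];
* the final score **S = ω₁ S₁(t\*) + ω₂ S₂**.

Rankings can be evaluated against positive/negative motif labels with
ROC/AUC (motif-level or per-family best rank). A synthetic-data module
generates background genomes with a planted co-motif at exponentially
distributed distances from the peaks, so the whole pipeline is testable
without downloads. See the vignette
(`vignettes/adjacency-scoring.Rmd`) for the model, parameter defaults
and design rationale.

## Worked example

```r
library(coTFscan)

## motifs in TRANSFAC format
motifs <- read_transfac(system.file("extdata", "example_motifs.transfac",
                                    package = "coTFscan"))
motifs[[1]]
#> Motif frequency matrix 'SYN$BHLH_01' (10 bp)
#>   [,1] [,2] [,3] [,4] [,5] [,6] [,7] [,8] [,9] [,10]
#> A  0.2  0.4  0.0    1    0    0  0.0    0  0.2   0.2
#> C  0.4  0.2  0.8    0    1    0  0.2    0  0.0   0.2
#> G  0.2  0.2  0.0    0    0    1  0.0    1  0.6   0.4
#> T  0.2  0.2  0.2    0    0    0  0.8    0  0.2   0.2

## a synthetic dataset: 200 peaks, one planted 10-mer, 5 decoys
spec <- synthetic_spec(seed = 7, n_peaks = 200, m = 500,
                       plant_prob = 0.8, lambda = 50, n_decoys = 5)
ds <- generate_dataset(spec)
windows <- extract_windows(ds$genome, ds$peaks, m = 500)
ranking <- score_motifs(windows, ds$motifs, scoring_config(m = 500, b = 20))
print(ranking, digits = 3)
#>   rank motif_id       S      S1   S2 t_star     r  b   n
#> 1    1  PLANTED  2.8142  2.7616  0.5   5000 10000 20 200
#> 2    2 DECOY_05  0.1050 -0.0529  1.5    100 10000 20 200
#> 3    3 DECOY_01  0.0915  0.0388  0.5    100 10000 20 200
#> 4    4 DECOY_03 -0.0907 -0.0380 -0.5    100 10000 20 200
#> 5    5 DECOY_02 -0.3090 -0.1511 -1.5    100 10000 20 200
#> 6    6 DECOY_04 -0.3936 -0.1304 -2.5    100 10000 20 200
roc_auc(ranking, ds$labels)
#> [1] 1
```

The planted co-motif tops the ranking with S an order of magnitude above
the decoys: its strongest sites sit in the peak-proximal bins, so the
top-row differences between adjacent bins are large and positive, while
decoys fluctuate around zero. With the planted motif labeled positive and
decoys negative, the AUC of the ranking is 1. Scores per motif report the
selected depth `t_star`, the matrix depth `r`, bin count `b` and number
of windows `n`.

A command-line front end wraps the same functions
(`inst/cli/cotfscan.R`; subcommands `simulate`, `score`, `eval`,
`diagnose`):

```sh
Rscript inst/cli/cotfscan.R simulate --seed 1 -o synth
Rscript inst/cli/cotfscan.R score --genome synth/genome.fa \
    --peaks synth/peaks.bed --motifs synth/motifs.transfac -o scores.tsv
Rscript inst/cli/cotfscan.R eval --scores scores.tsv --labels synth/labels.tsv
```

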