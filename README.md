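# grinch

Simultaneous smoothing and TAD calling on chromatin contact matrices by
graph-regularized non-negative matrix factorization.

Hi-C and related assays (SPRITE, HiChIP) measure chromosome organization
as a symmetric matrix X of contact counts between fixed-width genomic
bins. Two analysis problems recur: segmenting the chromosome into
topologically associating domains (TADs) — contiguous stretches of bins
that interact preferentially with one another — and denoising/imputing
sparse, low-depth count matrices. This package solves both with a single
model aimed at computational biologists working from chromosome-level
contact dumps.

## The model

The matrix is factorized as X ≈ UVᵀ with non-negative factors
U, V ∈ ℝ^(n×k), regularized so the latent features vary smoothly along the
chromosome. With W the chain adjacency (bins within r of each other),
D its degree matrix and L = D − W the graph Laplacian, the objective is

    ‖X − UVᵀ‖²_F + λ·Tr(VᵀLV) + λ·Tr(UᵀLU)

minimized by multiplicative updates

    u_ik ← u_ik (XV + λWU)_ik / (UVᵀV + λDU + ε)_ik
    v_jk ← v_jk (XᵀU + λWV)_jk / (VUᵀU + λDV + ε)_jk

from a deterministic NNDSVD initialization (randomized SVD + sign-split).
λ = 0 recovers plain NMF. The rows of U are then segmented into exactly
contiguous clusters — the TADs — by chain-constrained k-medoids, and the
symmetrized reconstruction (UVᵀ + VUᵀ)/2 is the smoothed, imputed matrix.

Also included, each behind its own function: mean- and Gaussian-filter
baseline smoothers, distance-stratified downsampling to a target depth
profile, a Poisson simulator with planted domains, and the TAD evaluation
suite (Davies–Bouldin index, delta contact count, Rand index, mutual
information, shuffled-TAD empirical significance, boundary fold
enrichment, hypergeometric tests, Jaccard overlap, AUPR).

## Worked example

Simulate a 6 Mb chromosome at 25 kb resolution with six planted 1 Mb
domains, then fit:

```r
library(grinch)

sim <- simulate_contacts(n_bins = 240, block_lengths = rep(40, 6),
                         alpha = 1, beta = 6, intensity = 50, seed = 3)
fit <- grinch(sim$matrix, r = 250000, lambda = 1,
              expected_tad_size = 1e6, seed = 3)
fit
#> GRiNCH fit
#>   chrS: 240 bins of 25,000 bp
#>   rank k = 6, radius = 10 bins, lambda = 1
#>   converged after 30 iterations, objective 3.69373e+07
#>   6 TADs called, median span 40 bins

tads(fit)
#>   start_bin end_bin cluster_id
#> 1         0      39          0
#> 2        40      79          1
#> 3        80     119          2
#> 4        120    159          3
#> 5        160    199          4
#> 6        200    239          5

rand_index(fit$labels, sim$labels)
#> [1] 1
```

The rank k = 6 was derived from the 1 Mb expected TAD size (240 bins ×
25 kb / 1 Mb); the radius of 250 kb couples each bin to its 10 neighbors
on each side. The six recovered TADs coincide exactly with the planted
blocks (Rand index 1 against the planted labels). `fitted(fit)` returns
the smoothed matrix, `tad_boundaries(tads(fit), 240)` the boundary bins
used by the enrichment metrics, and `plot(fit)` a heatmap with the TADs
outlined.

Real matrices are read with
`read_contact_matrix("chr1.txt", "triple", bin_size = 25000)` (Rao-style
`start1 TAB start2 TAB count` dumps, or dense square matrices) and TADs
written as BED with `write_tads_bed()`.

A command-line wrapper over the same functions is installed with the
package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "grinch.R", package="grinch"))')" \
  call-tads --matrix chr1.txt --format triple --bin-size 25000 \
  --chrom chr1 --radius 250000 --lam 1 --seed 42 --out-prefix chr1_run
```

Subcommands: `call-tads`, `smooth`, `filter`, `downsample`, `evaluate`,
`simulate`.

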