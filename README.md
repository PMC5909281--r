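# pooldecon

Estimate the proportion of each known donor in a pooled DNA sample from
low-coverage whole-genome sequencing, without barcodes.

## The problem

Screening cells from many donors one donor at a time is slow.  If the
donors' genomes are already known (genotyping array or WGS), their
common single-nucleotide polymorphisms act as a natural barcode: pool
the cells, extract and sequence the pooled DNA shallowly, tally the
reference/alternate reads at known bi-allelic autosomal SNPs, and infer
each donor's share of the pool.  Case/control pools (e.g. before and
after selection or FACS sorting) then give a per-donor phenotype from a
single experiment.

`pooldecon` is for anyone running such multiplexed donor experiments:
it takes a donor genotype panel (VCF or TSV) plus per-SNP pooled allele
counts (TSV or samtools-mpileup text) and returns the donor proportion
vector, with the simulation and evaluation machinery used to validate
the method.

## The estimator

For donors n = 1..N with R-allele dosage d<sub>mn</sub> ∈ {1, 0.5, 0}
(genotype RR/RA/AA) at SNP m, each pooled read at m is modelled as
coming from donor n with probability θ<sub>n</sub> and showing the R
allele with probability d<sub>mn</sub>, so the expected R fraction is
Total<sub>m,R</sub> = Σ<sub>n</sub> d<sub>mn</sub> θ<sub>n</sub>.
Starting from θ<sub>n</sub><sup>0</sup> = 1/N, expectation–maximization
re-apportions the observed counts into per-donor scores

L<sub>n</sub> = Σ<sub>m</sub> θ<sub>n</sub> ·
[ d<sub>mn</sub>·Reads<sub>m,R</sub>/Total<sub>m,R</sub> +
(1−d<sub>mn</sub>)·Reads<sub>m,A</sub>/Total<sub>m,A</sub> ]

and updates θ<sub>n</sub><sup>t+1</sup> = L<sub>n</sub> / Σ L<sub>n</sub>
(2000 iterations by default; each iteration ascends the observed-data
likelihood).  With ≥ 500,000 SNPs, pools of 100 donors are recovered
accurately even at 1X coverage; accuracy falls as the donor count grows
and rises with depth and SNP count.

## Worked example

```r
library(pooldecon)

# a pool of 10 donors, 500,000 SNPs, sequenced at 1X
sim <- simulate_pool(n_donors = 10, n_snps = 500000, depth = 1, seed = 1)
fit <- pool_em(sim$panel, sim$counts, iterations = 500)
fit
#> Pooled-sample donor proportion estimate (EM)
#>   10 donors, 500000 SNPs, 500000 reads
#>   500 iterations (fixed budget), final max change 3.09e-10
#>   largest proportions:
#>  donor9  donor4  donor6 donor10  donor2  donor1 
#> 0.17306 0.15317 0.11528 0.11226 0.10268 0.09030 

evaluate_recovery(sim$true_theta, fit)
#> Parameter-recovery report
#>   donors: 10   Pearson R: 0.9997   max |error|: 0.001926
```

The estimate sums to 1 across donors; `evaluate_recovery()` compares it
with the simulation truth — here the correlation between true and
estimated proportions is 0.9997 and no donor is off by more than 0.2
percentage points, from single-read coverage.

On real data, build the inputs with `read_panel_vcf()` (bi-allelic
autosomal SNPs with complete genotypes) and `tally_pileup()` or
`read_counts_tsv()`, align them with `align_counts()`, and fit the same
way.  A command-line interface wrapping simulate/estimate/evaluate/grid
lives at `system.file("cli", "pooldecon.R", package = "pooldecon")`.

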