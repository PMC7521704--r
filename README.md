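# tilefs

Bayesian discovery of functional sequences — enhancers, silencers,
promoter-proximal elements — from **pooled tiling CRISPR screens**
(CRISPRi, CRISPRa, Cas9). The package is aimed at regulatory-genomics
labs analysing screens in which thousands of sgRNAs tile a candidate
region and cells are sorted into pools (FACS expression bins, or
before/after proliferation pools), so that the only data are per-sgRNA
read counts across pools and the locations of functional elements are
unknown.

## The model

The screened region is divided into *M* non-overlapping genome segments
(default 100 bp). Each sgRNA *n* perturbs an **area of effect** around
its target site (default ±200 bp), overlapping the segment set *g(n)*.
Counts **y**<sub>n</sub> for sgRNA *n* across the *J* pools follow a
Dirichlet-multinomial (DMN) mixture:

- *r*<sub>n</sub> ~ PoissonBinomial(**p**<sub>g(n)</sub>) — the number of
  functional segments the guide overlaps, where *p*<sub>m</sub> is the
  probability segment *m* contains any functional sequence;
- **y**<sub>n</sub> | *r*<sub>n</sub> = 0 ~ DMN(**α**<sub>0</sub>)
  (background sorting), and
  **y**<sub>n</sub> | *r*<sub>n</sub> > 0 ~ DMN(**α**<sub>1</sub>)
  (functional sorting).

The Dirichlet shape vectors **α**<sub>0</sub>, **α**<sub>1</sub> encode
both the expected pool proportions and the overdispersion, and are
estimated by maximum likelihood (L-BFGS-B over log-shapes) with the help
of known positive-control regions (e.g. the target-gene promoter),
whose segments are fixed at probability 1 in row π<sub>0</sub>.

*K* functional sequences of length 1…*L* segments (default *L* = 10,
truncated-geometric length prior) are localised by **iterative Bayesian
stepwise selection**: one sequence at a time, its exact placement
posterior over all (start, length) placements is computed conditional on
the probabilistic placements of the others, and the per-segment
probability matrix **π** is updated until convergence. *K* itself is
chosen by increasing K until the rows of **π** start to co-locate —
the largest K whose maximum pairwise Pearson correlation stays below
0.1. Each sequence is reported as a 95% credible region.

The package also ships a full **screen simulator** with known ground
truth (ZINB sgRNA library → multinomial input pool → Dirichlet-
multinomial FACS sorting scaled by guide efficiency *f*<sub>n</sub> and
element strength *h*<sub>k</sub> → hypergeometric/multinomial
sequencing) and the standard **evaluation metrics** (average precision,
precision, recall, base-pair accuracy).

## Worked example

Simulate a 4-pool expression screen (~1,700 sgRNAs tiling 30 kb, eight
planted 50 bp enhancers, strong selection, high guide efficiency), then
fit the model with automatic selection of K:

```r
library(tilefs)

config <- sim_preset("facs_small", seed = 7)
sim <- simulate_screen(config)

# positive-control region: the known element +/- 1 kb (promoter convention)
promoter <- data.frame(chrom = "chrS",
                       start = sim$truth$fs0$start - 1000,
                       end   = sim$truth$fs0$end + 1000)

fit <- fs_screen(sim$data, promoter, k_max = 12)
fit
#> Tiling-screen functional sequence fit
#> Call:  fs_screen(counts = sim$data, controls = promoter, k_max = 12)
#>
#> 1700 sgRNAs, 4 pools, 302 segments of 100 bp
#> K = 8 (selected by pairwise correlation)
#> 8 credible region(s) at 0.95 coverage

coef(fit)   # fitted Dirichlet shapes (input, low, medium, high pools)
#>            [,1]     [,2]     [,3]     [,4]
#> alpha0 15.29908 15.60914 15.72643 13.50789
#> alpha1 21.84939 19.37599 19.04611 24.76857

head(fit$regions)
#>   fs chrom start   end posterior diffuse
#> 5  5  chrS     0   800 0.9753260   FALSE
#> 3  3  chrS  1300  2400 0.9746144   FALSE
#> 1  1  chrS  3600  4300 0.9731659   FALSE
#> 4  4  chrS  5300  6100 0.9650450   FALSE
#> 6  6  chrS  6800  7500 0.9653166   FALSE
#> 2  2  chrS 10700 11600 0.9663838   FALSE

evaluate_fit(fit$fit, sim$truth)
#>   average_precision precision recall_count bp_accuracy n_fs_true
#> 1         0.1187567         1            8  0.06349206         8
```

All eight planted enhancers are recovered (recall 8/8, precision 1):
α̂<sub>1</sub> shifts mass toward the high-expression pool, exactly the
signature the simulator plants. BP accuracy is bounded well below 1 here
because the simulated area of effect (±500 bp) is much wider than the
50 bp elements — a guide half a kilobase away still carries signal, so
called regions are necessarily wider than the elements themselves.

`run_pipeline()` performs the same analysis file-to-file, writing one
bedGraph track per functional sequence, a combined probability track, a
BED6 of credible regions, the full probability matrix as CSV, and
K-selection diagnostics. Thin command-line wrappers live in
`inst/scripts/` (`simulate_screen.R`, `run_screen.R`,
`evaluate_screen.R`).

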