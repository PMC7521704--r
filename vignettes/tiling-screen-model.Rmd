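---
title: "Modelling tiling CRISPR screens with tilefs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling tiling CRISPR screens with tilefs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A tiling CRISPR screen perturbs every position of a candidate regulatory
region with thousands of overlapping sgRNAs and reads out a phenotype by
sorting cells into pools — FACS bins of a reporter gene's expression, or
before/after pools of a proliferation screen. The data are a table of
per-sgRNA read counts across pools. The analysis task is the reverse
inference: which small stretches of the region (candidate enhancers,
silencers, promoter-proximal elements) changed the phenotype when
perturbed, given that each sgRNA's area of effect covers several hundred
base pairs and overlapping guides blur each other's signals.

`tilefs` addresses this with a generative count model and a stepwise
Bayesian placement algorithm, fitted by `fs_screen()`.

# The count model

The screened span is tiled into $M$ non-overlapping segments of
`segment_size` bp (default 100). Guide $n$'s area of effect — its target
site extended by `effect_range` bp on each side (default 200, i.e. a
400 bp window appropriate for dCas9 effector domains; ~10 bp suits Cas9
indel screens) — overlaps the segment set $g(n)$.

Counts are modelled conditional on each guide's total, so library-size
differences between guides drop out. With $p_m$ the probability that
segment $m$ contains a functional sequence,

$$r_n \sim \mathrm{PoissonBinomial}\big(p_{g(n)}\big), \qquad
\mathbf{y}_n \mid r_n = 0 \sim \mathrm{DMN}(\boldsymbol\alpha_0), \qquad
\mathbf{y}_n \mid r_n > 0 \sim \mathrm{DMN}(\boldsymbol\alpha_1).$$

Only $\Pr(r_n = 0) = \prod_{m \in g(n)} (1 - p_m)$ is needed, so the
Poisson-binomial never has to be evaluated beyond its zero mass. The
Dirichlet-multinomial marginalises the per-guide sorting probabilities
analytically; its $J$ shape parameters jointly encode the expected pool
proportions ($\alpha_j / \sum_j \alpha_j$) and the overdispersion (the
concentration $\sum_j \alpha_j$), which real sorted count data always
show relative to a multinomial. Non-targeting sgRNAs are dropped on
input: having no genomic target, they inform neither component.

$\boldsymbol\alpha_0, \boldsymbol\alpha_1$ are estimated by maximum
likelihood on the full table with the placement probabilities held
fixed, using L-BFGS-B over $\log \boldsymbol\alpha$ — the log
parameterisation enforces positivity and gives a smoother landscape than
box constraints. Analytic gradients use the digamma function; the
method-of-moments start takes the empirical pool proportions of
control-overlapping guides (for $\boldsymbol\alpha_1$) and all remaining
guides (for $\boldsymbol\alpha_0$) at concentration 10. Convergence is a
projected-gradient tolerance of $10^{-6}$ or 500 iterations. A pool with
all-zero counts would drive its shape to 0; shapes are floored at
$10^{-6}$ with a warning. All-zero guides are retained — they contribute
probability 1 under both components and therefore no information.

The semi-supervision comes from positive controls: segments overlapping
a user-supplied control region (typically the target-gene promoter) are
fixed at probability 1 in row $\pi_0$. The control region should cover
*all guides dominated by the known element* — the promoter ± 1 kb
convention, not the minimal element — otherwise guides whose areas of
effect graze the element look like novel signal beside it.

# Stepwise placement

A placement of functional sequence $k$ is a start segment and a length
$l \in \{1, \dots, L\}$ (default $L = 10$, i.e. up to 1 kb at the
default grid). Exact joint inference over all $K$ sequences is
intractable — even $K = 5$ single-segment sequences among $10^4$
segments admit $\binom{10^4}{5} \approx 8\times10^{17}$ configurations
(`n_configurations()`). Instead, one sequence at a time is re-placed:
its row of the probability matrix $\boldsymbol\pi$ is zeroed, the
combined probability of the *other* rows gives each segment's
$p_m = \min(1, \sum_{k'} \pi_{k',m})$, and the posterior over every
placement of sequence $k$ is computed exactly under that background.
Row $k$ is then the coverage projection of that posterior, so its total
equals the posterior expected length ($\in [1, L]$). Hyperparameters are
re-fitted once per outer sweep, before the row updates, following the
algorithm's printed form; iteration stops when
$\max|\boldsymbol\pi' - \boldsymbol\pi| <$ `tol` (default $10^{-3}$,
`max_iter` 100).

Because a hard placement sets its segments to probability 1, every guide
overlapping it collapses to the functional component exactly; guides
elsewhere keep their baseline mixture term. The placement likelihood
table is therefore a base value plus per-guide gains accumulated with
prefix sums over the (contiguous) guide windows — identical to the naive
product over all guides, which the tests verify to $10^{-8}$, but
evaluated in $O(N + ML)$ per row update.

The length prior is a geometric distribution truncated at $L$,
$w_l \propto (1-\lambda)^{l-1}\lambda$ (default $\lambda = 0.1$, mean
≈ 4.5 segments under truncation), uniform across placements of the same
length. Edge effects shrink the number of valid long placements;
normalisation is within the valid set.

**Choice of K.** Fits are run at $K = 1, 2, \dots$; once K exceeds what
the data support, newly added sequences co-locate with existing ones and
rows of $\boldsymbol\pi$ become correlated. The selected K is the
largest whose maximum pairwise Pearson correlation (zero-variance rows
count as 0) stays below `corr_threshold` = 0.1. Successive fits are
warm-started from the previous K's rows for speed; `warm_start = FALSE`
restores literal cold starts, and the exact-equivalence tests use fixed
hyperparameters so the single-sweep posterior can be checked against
brute-force enumeration.

**Reported regions.** Each sequence's 95% credible region greedily
accumulates placements by descending posterior (ties broken by smaller
start, then shorter length) and reports the union of covered segments as
intervals, merging adjacent segments. Regions wider than
`diffuse_width` (50 segments) are flagged as diffuse/unsupported in the
summary.

## Design choices that were genuinely open

- **Overlap clipping.** When probabilistic placements overlap,
  $\sum_k \pi_{k,m}$ can exceed 1; it is clipped to 1 before the
  Poisson-binomial step so $p_m$ stays a probability. This is the
  minimal intervention that preserves the defining formula whenever the
  sum is below 1.
- **Control segments as candidates.** Segments fixed at 1 in $\pi_0$
  are excluded as candidate placements for the free sequences
  (`exclude_fs0 = TRUE`): their probability is already 1, so placements
  there only waste posterior mass. Configurable off.
- **Replicates.** All pools of all replicates enter as the $J$ columns
  of one Dirichlet-multinomial; there are no per-replicate
  hyperparameters.
- **Coordinates.** 0-based half-open everywhere internally and in
  BED/bedGraph output; `read_screen_counts(one_based = TRUE)` converts
  1-based-inclusive tables on input.

# The screen simulator

`simulate_screen()` generates datasets with known truth by mimicking the
experiment stage by stage:

1. **Library.** Per-guide counts are zero-inflated negative binomial
   (`fit_zinb()` estimates $\mu, d, \varepsilon$ from a real library by
   maximum likelihood). Defaults $\mu = 300$, $d = 2$, $\varepsilon =
   0.05$ give the long-tailed representation with a few percent dropout
   typical of plasmid libraries.
2. **Input pool.** Multinomial sampling of `n_cells` cells from the
   library frequencies; the default coverage of 2,000 cells per guide
   keeps every FACS bin deep enough to sequence without replacement at
   the default depth.
3. **Sorting.** For a guide with element strength $h$ (the maximum over
   elements its simulation-scale area of effect overlaps; the central
   positive-control element has $h = 1$), $w = \mathrm{round}(c f_n)$
   cells carry an effective guide and sort by a Dirichlet-multinomial
   with shapes $\boldsymbol\alpha + h\,\mathbf{T}$; the remaining cells
   sort with $\boldsymbol\alpha$. Efficiency partitions cells
   deterministically via the rounding rather than binomial thinning,
   matching the defining equation. Guide efficiencies are
   Beta-distributed (presets low/medium/high = Beta(2,5)/(5,5)/(5,2)),
   element strengths Beta(3,3) (weak) or Beta(8,2) (strong), and the
   selection strength adds Dirichlet mass 2 (weak) or 10 (strong) on
   the phenotype-relevant pool against a symmetric background of 10s.
4. **Sequencing.** `depth` reads per guide per pool (presets medium =
   100, high = 400), drawn multivariate-hypergeometrically without
   replacement (UMI-style deduplicated reads) or multinomially with
   replacement.

The simulation area of effect defaults to ±500 bp (CRISPRi/CRISPRa;
±20 bp for Cas9), deliberately wider than the analysis default — signal
bleeds further than the analysis window assumes, as in real effector
screens. Elements are placed uniformly at random with a minimum gap of
twice the simulation effect range so neighbouring signals remain
resolvable; the positive-control element (500 bp, $h = 1$) sits at the
region's centre, standing in for the target-gene promoter. Expression
screens emit the pre-sort pool as a shared `input` column plus one
column per FACS bin and replicate; selection screens emit
before/after columns per replicate.

**What the simulator does not emulate:** PCR amplification bias,
multiple infection/doublets, position-dependent guide efficiency,
off-target cutting, chromatin context, and replicate-specific sorting
drift. Passing tests on simulated data therefore demonstrate correct
recovery under the stated generative assumptions, not robustness to
these real-data artefacts.

# Numerical choices

Placement posteriors are normalised in log space with log-sum-exp;
probabilities from coverage projections are clamped to $[0,1]$ against
round-off; the DMN is evaluated entirely through `lgamma`. Greedy
credible-set ties break deterministically (smaller start, then shorter
length), and nothing in the fit consumes random numbers, so identical
inputs give bit-identical results; all simulator randomness flows from
one seed.

Test and example problem sizes were chosen so the whole suite exercises
every path at desk scale: the scaled study design uses a 30 kb region
with ~1,700 evenly tiled guides and eight 50 bp elements (the full-size
preset, 150 kb/8,700 guides, is generated and dimension-checked), exact
enumeration checks use $M \le 8$, $L \le 2$ toys, and hyperparameter
recovery uses 2,000 background plus 200 control guides.

# Known limitations

- **The model always places exactly K sequences.** On data with no real
  signal the placement posterior still concentrates on the most
  signal-like noise cluster, because the functional component's
  dispersion is free to shrink onto quasi-typical guides. The
  informative null diagnostic is the evidence gain — the log-likelihood
  gained over the controls-only fit is near zero on null data and large
  when an element is real — together with the diffuse-region flag.
  There is no calibrated false-discovery control.
- Guide efficiency and off-target effects are not modelled in the
  analysis (only in the simulator); a single functional component is
  shared by all elements, so strong and weak elements are not
  distinguished.
- Resolution is bounded by the segment grid and the area of effect: a
  50 bp element wholly inside one called 100 bp segment caps base-pair
  accuracy at 50%, and at 25% when split across two called segments.
- The correlation rule for K assumes distinct elements occupy distinct
  segments; elements closer than the area of effect merge into one
  credible region.
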