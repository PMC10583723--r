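# batchalloc

Batch allocation for observational studies with sequential sample
processing.

In a designed experiment you assign treatments to subjects; in an
observational omics study the cohort is fixed and the design question is
the reverse: **which samples should be processed together?** Samples are
processed in batches (plates, mass-spectrometry runs, bench days) of
limited size, batch effects are real, and a careless split makes treatment
and batch effects inseparable. `batchalloc` is for the statistician or lab
scientist who has a table of samples with one nominal treatment variable
(disease group, exposure, genotype) and a maximum batch size, and needs a
reproducible, well-balanced assignment of samples to batches plus a
randomized processing order.

## The method in brief

An allocation of $T$ treatments (counts $t_1,\dots,t_T$) to $B$ batches
(sizes $b_1,\dots,b_B$, with $\sum t_i = \sum b_k$) is a $B\times T$
incidence matrix $N$. Its quality is the D-criterion
$\lvert X^\top X\rvert$ of the model
$y=\mu+\text{treatment}+\text{batch}+\varepsilon$ — zero means confounding,
larger means smaller generalized variance of the estimates. Exhaustive
search over the $\prod_k\binom{T}{b_k}$ allocations is hopeless beyond toy
sizes, so the package implements:

* **preallocation** — every batch gets $\lfloor t_i/B\rfloor$ subjects of
  treatment $i$ up front, reducing the rest to a binary problem;
* **SBA**, a stochastic heuristic that fills one batch at a time, guided by
  the concurrence matrix $\Lambda=N^\top N$ (how often each treatment pair
  already shares a batch): feasibility-forced treatments first, then
  never-chosen treatments, then minimum-concurrence pairs and lowest
  column sums, all ties broken at random;
* **RBA**, the random-binary baseline it is compared against;
* **exact integer scoring** of $\lvert X^\top X\rvert$ (modular arithmetic +
  CRT — large-setting scores are 22-digit integers that doubles cannot
  compare), simple-contrast variances, and an exhaustive optimizer for
  small instances;
* a multi-run **evaluation harness** (best-of-n, run-until-stable, run-level
  comparisons) and **post-allocation randomization**: batch order, subject
  assignment, within-batch processing order.

## A worked example

Five disease groups with 6, 7, 8, 8 and 9 samples; at most three samples
can be processed together:

```r
library(batchalloc)
p <- allocation_problem(c(ctrl = 6, dis1 = 7, dis2 = 8, dis3 = 8, dis4 = 9),
                        max_batch_size = 3)
p
#> Batch allocation problem
#>   treatments: ctrl (6), dis1 (7), dis2 (8), dis3 (8), dis4 (9)
#>   batches:    13 with sizes 3 3 3 3 3 3 3 3 3 3 3 3 2

search_space_size(p)   # exhaustive search is out of the question
#> [1] "10000000000000"

best <- best_of_n(p, "sba", n = 200, seed = 42)
best
#> Scored allocation (sba, seed 1781592037): D = 309416760
#>       ctrl dis1 dis2 dis3 dis4
#>  [1,]    0    1    1    0    1
#>  [2,]    1    1    0    1    0
#>  ...
#> [13,]    0    0    0    1    1
```

Each row is a batch, each entry says how many samples of that group it
contains; the D-criterion 309 416 760 is the best of 200 heuristic draws
(the known best score for this cohort, 309 561 102, turns up within a few
thousand draws). The contrast variances show every pairwise group
comparison is estimated with similar precision:

```r
round(contrast_variances(best$incidence), 4)
#> ctrl-dis1 ctrl-dis2 ctrl-dis3 ctrl-dis4 dis1-dis2 dis1-dis3 dis1-dis4
#>    0.3777    0.3609    0.3656    0.3511    0.3176    0.3395    0.3090
#> dis2-dis3 dis2-dis4 dis3-dis4
#>    0.3044    0.2769    0.2740
```

Turn the allocation into a concrete, fully randomized processing plan for
named samples with `make_plan()` (or the `plan` subcommand below), which
shuffles batch order, assigns each sample to a slot of its treatment and
randomizes the order within every batch.

A command-line interface covering the same operations ships in
`inst/cli/batchalloc`:

```sh
inst/cli/batchalloc plan --manifest samples.csv --max-batch 8 --seed 1 --out plan.csv
inst/cli/batchalloc evaluate --setting A --algorithm sba,rba --runs 10 --allocs 100 --seed 1
```

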