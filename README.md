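# speechgraph

Non-semantic word-graph analysis of speech transcripts, for researchers
studying how discourse structure matures with age and education and how it
is altered in psychosis.

A transcript is represented as a directed multigraph: each distinct word is
a node, each consecutive word pair a directed edge (repeats accumulate
multiplicity, immediate repetitions become self-loops). Four attributes
summarize its structure, computed on 30-word moving windows with 50%
overlap and averaged per subject:

| attribute | meaning |
|---|---|
| **N** | lexical diversity — number of nodes |
| **RE** | short-range recurrence — sum of edge multiplicities over ordered pairs linked more than once |
| **LSC** | long-range recurrence — size of the largest strongly connected component |
| **ASP** | graph size — mean directed shortest path over reachable ordered pairs |

Attributes can be normalized against 100 word-shuffled null graphs per
window (distance from random structure), and their developmental
trajectory is modelled by binning at integer years *t* of age or education
and fitting the bounded, SEM-weighted saturating exponential

    f(t) = f0 + (f_inf − f0) · (1 − exp(−t/T))

with initial value `f0`, asymptote `f_inf`, and characteristic time `T`
(years). The package also ships the accompanying statistical battery
(Spearman and partial Spearman correlations, multiple regression,
Kruskal–Wallis + Wilcoxon with Bonferroni correction, KS/Levene checks,
proportion tests, temporal-order permutation nulls) and a synthetic-cohort
generator so the whole pipeline is testable without clinical data.

## Worked example

```r
library(speechgraph)

g <- word_graph(tokenize("the dog saw the dog and the cat"))
g
#> Word graph: 5 nodes, 7 edge instances ( 6 distinct ), 8 tokens
graph_attributes(g)
#>      N     RE    LSC    ASP
#> 5.0000 2.0000 4.0000 1.8125
```

`RE = 2` because the pair `the→dog` is traversed twice; `LSC = 4` because
`the, dog, saw, and` are mutually reachable; `ASP` averages the directed
shortest paths among reachable pairs.

A synthetic cohort end to end — controls mature with education,
psychosis-like subjects stay flat:

```r
coh <- generate_cohort(cohort_spec(n_control = 60, n_psychosis = 30), seed = 42)
tab <- analyze_cohort(coh, n_shuffles = 100, seed = 42)
ctl <- tab[tab$group == "control", ]

spearman(ctl$mean_N, ctl$education_years, alpha = 0.05, m = 8)
#> Spearman: statistic = 0.7711, p = 5.678e-13, n = 60, alpha = 0.0063 *

fit <- fit_maturation(mean_N ~ education_years, data = ctl)
fit
#> Saturating-exponential maturation fit: N ~ education_years
#>   f0 = 13.097, f_inf = 24.944, T = 2.67 y, |f_inf - f0| = 11.848
#>   R^2 = 0.8870, SSE = 25.8461, RMSE = 1.3127 on 18 bins (60 subjects)
```

Lexical diversity rises from ~13 to ~25 distinct words per 30-word window
with a characteristic time of ~2.7 years of education, and the rank
correlation with education survives a Bonferroni threshold of 0.0063
(0.05 over 8 comparisons). `plot(fit)` draws the binned means with SEM
bars and the fitted curve; `permute_time()` provides the
temporal-order-randomization null for rho and R².

Real data enter through `read_cohort(dir, "metadata.csv")` — UTF-8 `.txt`
transcripts (one per subject, or `_dream`/`_day`/`_image` report triples)
plus a CSV/TSV metadata table with `subject_id`, `group`, `age_years`,
`education_years` and optional covariates.

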