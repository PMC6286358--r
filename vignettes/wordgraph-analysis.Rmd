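---
title: "Non-semantic word-graph analysis of speech: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-semantic word-graph analysis of speech: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechgraph)
```

## The representation

A speech transcript is reduced to a directed word multigraph: every
distinct surface word is a node and every pair of consecutive words a
directed edge, with repeated traversals accumulating multiplicity and an
immediately repeated word forming a self-loop. No lemmatization, stemming
or stop-word removal is applied — the representation is deliberately
non-semantic, so that only the *trajectory* of the discourse through its
own vocabulary matters. Four attributes summarize that trajectory:

* **N** (nodes) — lexical diversity, the number of distinct words;
* **RE** (repeated edges) — short-range recurrence: the sum of edge
  multiplicities over ordered node pairs linked more than once;
* **LSC** — long-range recurrence: the node count of the largest strongly
  connected component, i.e. the largest set of words mutually reachable
  along directed edges. This is the attribute most associated with
  disorganized (psychotic) speech, where it is reduced;
* **ASP** — graph size: the mean directed shortest-path length over
  reachable ordered node pairs.

Because verbosity varies enormously between speakers (and with age), the
attributes are never computed on a whole transcript directly: the token
sequence is sliced into 30-word moving windows advancing 15 words (50%
overlap), the attributes are computed per window, and the per-subject
value is the mean across windows. A 30-word window bounds what each
attribute can attain: at most 30 nodes, exactly 29 edge instances, hence
RE at most 29.

### Dialect choices

The published definitions leave three details open; the package fixes them
as follows and exposes the alternatives as options.

* **RE.** "Sum of all edges linking the same pair of nodes" is read as
  the sum of multiplicities over ordered pairs with multiplicity at least
  two. This reading attains the edge-capacity bound of 29 in a 30-word
  window (e.g. one word repeated 30 times); the alternative reading
  (total instances minus distinct pairs, maximum 28) is available as
  `re_mode = "excess"`. Pairs are ordered — `a→b` and `b→a` count
  separately — because the graph is directed.
* **ASP.** Computed on the directed graph; ordered pairs with no directed
  path are excluded from the mean, because children's word graphs are
  frequently not strongly connected and any finite placeholder would
  dominate the average. A graph with no reachable pair has ASP 0, with a
  warning. `asp_mode = "undirected"` measures the underlying undirected
  graph instead. Self-loops never contribute (only pairs `u != v`).
* **Tokens.** Maximal runs of Unicode letters/digits with internal
  apostrophes and ASCII hyphens, lower-cased; `split_joiners = TRUE`
  splits on those joiners instead, since transcription conventions differ.

Edge multiplicities matter only for RE; LSC and ASP are topological.

## The shuffle null

To measure distance from random structure, each 30-word window is shuffled
(the word multiset kept, the order randomized — equivalent to a random
permutation of edges) `n_shuffles = 100` times; attributes of the shuffled
graphs are averaged into a per-window denominator and the observed value is
divided by it. The per-window ratios are averaged per subject
(`normalize_by = "window"`; computing both means first and taking a single
ratio is available as `"subject"`). Shuffling preserves the node set, so
the normalized N is exactly 1 — a useful internal control. Windows whose
denominator is zero for an attribute (e.g. RE on an all-distinct window)
are skipped for that attribute and counted, rather than patched with a
pseudo-count that would bias the ratio.

Randomization is reproducible: one master seed per run, with per-subject
streams derived deterministically from the subject id, so results do not
depend on the order in which subjects are processed.

## The maturation model

Attribute values are binned at integer years of age or education, and the
bin means are fit with the saturating exponential

$$f(t) = f_0 + (f_\infty - f_0)\,\bigl(1 - e^{-t/T}\bigr),$$

the solution of $df/dt = (f_\infty - f)/T$ with $f(0)=f_0$: early
accelerated development followed by saturation, with $T$ the number of
years at which $1-e^{-1}\approx 63\%$ of the total change is reached. The
fit (`fit_maturation()`) is a bounded, weighted nonlinear least squares:

* **weights** $1/\mathrm{SEM}^2$ (inverse variance; $1/\mathrm{SEM}$ as an
  option). Single-subject bins have no SEM and receive the largest SEM
  observed among multi-subject bins — the weakest finite weight — so that
  sparse old-age bins inform the asymptote without being dropped or given
  infinite influence. Zero SEMs (noiseless simulations) are replaced by
  the smallest positive SEM, or unit weights if none exists.
* **bounds** $f_0, f_\infty \in [0, 30]$ for node-counted attributes (N,
  LSC) and $[0, 29]$ for edge-counted ones (RE, ASP) — the capacities of a
  30-word window — and $T \in [0, 30]$ years for both time variables
  (education reaches post-doctoral levels near 30 years; the same cap is
  reused for age). The lower bound of $T$ is implemented as $10^{-6}$
  since the curve is undefined at $T = 0$.
* **start points**: $f_\infty$ at the maximum observed bin mean, $f_0$ at
  the minimum, $T = 12$ years.
* **optimizer**: Levenberg–Marquardt with box constraints
  (`minpack.lm::nlsLM`), with up to 10 uniformly jittered restarts when a
  start fails — three-parameter exponentials are multimodal under noise —
  keeping the best weighted SSE. If every gradient-based attempt fails
  (e.g. a perfectly flat series makes $T$ unidentifiable), a bounded
  L-BFGS-B minimization of the same objective supplies the coefficients.

Goodness of fit is reported on the *unweighted* bin means:
$R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ (defined as 0 for a flat series,
and possibly negative for a fit worse than the mean),
$\mathrm{RMSE} = \sqrt{\mathrm{SSE}/(n_\mathrm{bins}-3)}$. The weighted
SSE is retained alongside (`$wsse`). The amplitude $|f_\infty - f_0|$ is
the model's summary of how much an attribute matures: the central clinical
prediction is that it is large in typical development and small in
psychosis, with $f_\infty > f_0$ for N, LSC and ASP and $f_0 > f_\infty$
for RE.

The companion null (`permute_time()`) randomizes the temporal variable
across subjects (1000 times by default) and recomputes both the
subject-level Spearman correlation and the binned-fit $R^2$ per surrogate;
destroying temporal order should abolish both when a real trend exists.
Empirical p-values use the add-one convention.

## The statistical battery

All group-level statistics go through the standard R machinery
(`kruskal.test`, `wilcox.test`, `ks.test`, `chisq.test`, `lm`,
`car::leveneTest`) behind thin wrappers that attach the Bonferroni context:

* Spearman correlations use midranks with the two-sided t approximation
  (an exact permutation p is available behind `exact_perm = TRUE`);
* the partial Spearman correlation is the first-order Pearson partial on
  midranks, with a t-test on $n-3$ degrees of freedom; a constant
  adjustment variable degrades gracefully to the plain correlation,
  whereas an exactly monotone one leaves the partial undefined (error);
* Wilcoxon rank-sum tests use the exact distribution when both groups have
  at most 10 observations and the tie/continuity-corrected normal
  approximation otherwise;
* Levene's test is mean-centered by default (classic), median-centered
  (Brown–Forsythe) on request;
* the one-sample Kolmogorov–Smirnov normality check estimates the normal
  moments from the sample and is flagged approximate (conservative in the
  Lilliefors sense); the calibrated two-sample variant is provided
  separately;
* the 2×2 proportions chi-square is uncorrected by default (Yates
  correction optional);
* `bonferroni(alpha, m)` returns the exact `alpha/m` (0.05/8 = 0.00625,
  conventionally displayed as 0.0063; 0.05/4 = 0.0125).

## The synthetic cohort generator

Real transcripts from clinical cohorts are not redistributable, so the
package ships a generator whose output has the statistical structure the
pipeline assumes, making every stage testable offline. Each transcript is
emitted token by token from a three-way mixture with one dial per
recurrence axis: novelty (`theta_new`, a previously unseen word from a
Zipf-weighted pool — drives N), perseveration (`theta_persev`, re-emitting
the successor of the current word's previous occurrence, reproducing an
earlier bigram — drives RE), and long-range return (`theta_return`, a jump
to a uniformly chosen earlier word, closing large cycles — drives LSC and
ASP); residual mass repeats a recent word. The mechanism is intentionally
*not* a language model: the dials are independent and interpretable, and
no training data are needed.

A cohort couples the dials to demographics. Ages are uniform on 2–58
years; education is age minus a schooling start of 6 years (capped at 22,
minus a small completion lag), truncated for school dropouts, which occur
with probability 0.28 in controls and 0.62 in the psychosis-like group.
For controls each dial follows the saturating exponential *in education
years* — the package's reading of the developmental claim that education,
not age per se, drives discourse maturation — with defaults

| dial | $f_0$ | $f_\infty$ | $T$ (yE) |
|---|---|---|---|
| `theta_new` | 0.35 | 0.62 | 2 |
| `theta_persev` | 0.40 | 0.03 | 1.5 |
| `theta_return` | 0.04 | 0.30 | 10 |

chosen so that lexical diversity rises and perseveration falls within the
first school years while long-range recurrence saturates around high
school, and so that the three probabilities always sum below 1.
Psychosis-like subjects keep the flat child-like level $f_0$ regardless of
age or education. Per-subject Gaussian jitter (`noise_sd = 0.03`) spreads
individuals around the trajectory. Transcripts default to 300 tokens
(roughly three short concatenated reports, ~19 windows); the verbosity
distribution of real cohorts is unknown, so length is a free parameter.

What the generator does **not** emulate: syntax, semantics, topic
structure, age-dependent verbosity, or the absolute attribute magnitudes
of any real cohort. Tests passing on synthetic cohorts therefore establish
that the pipeline's machinery is correct and directionally sensitive — not
that any particular clinical effect size would replicate.

## Problem sizes and verification

The shipped checks use: a 200-subject cohort (135 controls / 65
psychosis-like, 300 tokens each) at 100 shuffles per window; brute-force
reachability and breadth-first-search oracles on 200 random sequences of
length ≤ 12 (with an igraph cross-check); 100-replicate parameter recovery
on 20-bin series (10 subjects/bin, noise SD 0.2), where all three
parameters are recovered with median relative error well under 10% and the
noiseless case to better than $10^{-4}$; 1000-fold temporal-order
randomization; and 1000-replicate null simulations confirming each test's
type-I error at the nominal 5% level. `scripts/acceptance.R` reruns the
main quantities end to end from a single seed.

## Known limitations

* The attribute dialect (RE reading, directed ASP with exclusion of
  unreachable pairs) matches the stated definitions and capacity bounds
  but other implementations may differ on these unstated details; the
  options above exist precisely to bracket that uncertainty.
* $R^2$ for a nonlinear fit is a descriptive quantity; comparisons should
  stay within a fixed binning and weighting convention.
* The one-sample KS normality check with estimated moments is
  conservative; it motivates the nonparametric battery rather than
  providing a calibrated test.
* Windowed means from short transcripts (a single flagged short window)
  are noisy and comparable only with caution.
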