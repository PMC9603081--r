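---
title: "Motif enrichment in small promoter sets: the esdeg model and its choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif enrichment in small promoter sets: the esdeg model and its choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esdeg)
```

## The problem

Differential-expression experiments often end with a short gene list — a
few dozen genes — and the question of which transcription factors (TFs)
might drive the observed changes. The standard route is motif
over-representation: count binding-site predictions in the promoters of
the differential genes and compare against non-differential promoters.
With 20-odd promoters per group, contingency-table tests (Fisher's exact
test) have very little power, and the result depends strongly on the
arbitrary score threshold chosen for the position weight matrix (PWM)
scan.

`esdeg` addresses both problems at once:

1. **Threshold calibration by expected recognition rate (ERR).** For each
   motif, score thresholds are derived from the score distribution over
   the *whole promoter universe* (every annotated promoter, not just the
   study genes), so that thresholds are comparable across motifs of
   different lengths and information contents. A grid of 30 thresholds,
   log-equidistant in ERR between 5e-4 and 1e-4, replaces any single
   arbitrary cutoff.
2. **Monte-Carlo background resampling.** At each threshold level, the
   site frequency in the foreground promoters (`AV_FOR`) is compared with
   the distribution of frequencies over many background groups of the
   same size, drawn without replacement from non-differential genes:
   `Z = (AV_FOR - AV_BACK) / SD_BACK`, with a one-sided upper normal tail
   giving the per-level p-value. The group-size matching is what makes
   the test usable at n = 20.
3. **Hartung unification.** The 30 per-level p-values are strongly
   dependent (nested hit sets). Hartung's inverse-normal combination with
   an estimated inter-statistic correlation collapses them into one
   unified p-value per motif without assuming independence.
4. **Benjamini–Hochberg adjustment** across the motif collection controls
   the false discovery rate of the final ranked table.

A companion permutation test reports the pairwise similarity of the
enriched motifs, because PWM libraries are redundant: a block of
mutually similar enriched motifs (for instance the E-box variants bound
by bHLH-class TFs) is one biological signal, not many.

## The statistics in detail

### ERR calibration

For motif $m$ with log-odds weights $w$, every promoter of the universe
is scanned on both strands and all window scores pooled. For a nominal
rate $e$ on the grid, the threshold is the smallest observed score $t$
such that

$$\frac{\#\{\text{windows with score} \ge t\}}{\#\{\text{scored windows}\}} \le e ,$$

i.e. the realized ERR is the largest achievable that does not exceed the
nominal one (ties at $t$ all count as hits; if even the single best
window overshoots the budget the threshold is $+\infty$ and the level is
inert). Windows containing `N` are excluded from numerator and
denominator alike — masked sequence can never produce a hit.

The denominator counts *windows* (positions × strands), reading
"probability of site prediction" as a per-window probability. With
2001-bp promoters scanned on both strands, an ERR of 5e-4 corresponds to
roughly two expected hits per promoter, so the per-promoter presence
frequency (below) is already fairly saturated at the lenient end of the
grid and most discriminative at the strict end; the grid exists exactly
so that no single level has to be trusted.

### Site frequency and the Monte-Carlo comparison

The default "site frequency" of a group is the fraction of its promoters
containing at least one hit at the level's threshold — a per-promoter
presence fraction, robust to a single promoter carrying many sites. The
alternative `frequency = "window"` (hits per scanned window) is one
switch away and tested, for sensitivity analysis.

Background groups are drawn uniformly **without replacement** from the
background pool, each of exactly the foreground's size; `SD_BACK` is the
sample standard deviation (n − 1) over the `n_resamples` group
frequencies. When `SD_BACK` is zero the level is degenerate: the p-value
is 1 when the foreground is not above the background mean, and the
Monte-Carlo resolution floor `1/(n_resamples + 1)` when it is, with a
warning. One set of resampled gene groups is drawn per run and shared by
all motifs: the background groups are a property of the gene sets, not
of any motif, sharing them makes motif ranks comparable within a run,
and it is substantially cheaper.

The per-level p is the one-sided upper tail `1 - pnorm(Z)` — the method
reports over-representation; depletion is available behind
`alternative = "less"`.

### Hartung combination

With probits $t_i = \Phi^{-1}(p_i)$ over the $L$ levels, the
inter-statistic correlation is estimated as
$\hat\rho = 1 - \mathrm{var}(t)$, truncated below at $-1/(L-1)$, and

$$H = \frac{\sum_i t_i}{\sqrt{L + (L^2 - L)\left[\rho^* + \kappa\sqrt{\tfrac{2}{L+1}}(1-\rho^*)\right]}},
\qquad p_\text{unified} = \Phi(H),$$

with equal weights and $\kappa = 0.2$, a standard regularisation choice.
Two limiting cases anchor the implementation (and are tested): equal
p-values give $\rho^* = 1$ and return the common value unchanged, and a
single level returns its p directly. Inputs are clamped to
$[10^{-300}, 1 - 10^{-16}]$ before the probit transform, and the output
is floored at $10^{-300}$, so extreme enrichment never underflows to an
invalid zero. Because the levels are strongly dependent, the unified p
behaves like a stabilized "typical" per-level p, not like a product of
independent p-values — combining levels buys robustness against the
threshold choice, not a free sensitivity multiplier.

### Ranking and reporting

Motifs are sorted by BH-adjusted unified p, ties broken by unified p and
then motif id so output is deterministic; the printed table cuts at
`p_adj < 0.05` but the full table is always retained and written.

## Motif similarity

The enriched-motif table is shaded by a permutation test of pairwise
motif similarity. The score is the maximum, over all ungapped offsets
(overlap ≥ 4 columns) and both orientations, of the mean Pearson
correlation between aligned base-probability columns; the null
distribution re-scores against copies of the second motif whose columns
(positions) are permuted uniformly at random, and
$p = (1 + \#\{\text{null} \ge \text{observed}\})/(n_\text{perm} + 1)$.
Two conventions follow the enrichment-figure contract: cells with
$p > 0.05$ are printed empty ("significantly distinct" motifs), and the
matrix is symmetric with a significant diagonal. This column-permutation
test is a documented stand-in with the same interface and significance
convention as the external reference test it emulates; note that it is
conservative for motifs that share a column *multiset* (two E-box
variants with the same letters in different order can be called
distinct), which is the main reason the exact numeric shading of a
published figure is out of scope.

## The synthetic-data generator

Every statistical property of the package is testable without downloads
because the generator produces:

* **promoters** — i.i.d. mononucleotide sequences at configurable base
  frequencies (default uniform, length 2001 to match the (−2000; +1)
  promoter window);
* **planted sites** — drawn base-by-base from a motif's probability
  columns and written *over* the sequence at a uniform random offset
  (replacement, not insertion, so window bookkeeping stays aligned), with
  the ground truth returned;
* **DEG tables** — foreground genes receive the configured log2 fold
  change and `p_adj ~ U(0, 0.01)`; the rest receive
  `log2_fold ~ N(0, 0.1)` truncated to folds in [0.80, 1.25] and
  `p_adj ~ U(0.2, 1)`, so the default selection rules recover the planted
  partition exactly;
* **random decoy matrices** — one preferred base per position mixed with
  the uniform distribution (`random_pcm()`), giving decoys of moderate
  information content.

What the generator deliberately does **not** emulate: GC heterogeneity,
CpG islands, repeats, dinucleotide structure, and correlated gene
regulation. Passing tests therefore demonstrate the statistical
machinery (calibration, type-I error, power, determinism) under a
neutral background — they do not certify behavior under the
compositional biases of real genomes, where a GC-stratified background
pool would be the user's responsibility.

The packaged example motifs are synthetic E-box-type and AT-rich count
matrices written at column depths (~500) typical of curated ChIP-seq
libraries; shallow matrices smear the planted sites away from their own
consensus and are not representative of the libraries this tool is
meant to scan.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `upstream`, `downstream` | 2000, 1 | promoter window around the TSS; the (−2000; +1) convention includes the TSS base (width 2001). Whether +1 belongs in the window is genuinely ambiguous, hence configurable. |
| `err_max`, `err_min`, `n_levels` | 5e-4, 1e-4, 30 | the ERR grid (log-equidistant, endpoints included) |
| `p_max`, `min_fold` | 0.1, 2.0 | foreground criteria: `p_adj < p_max`, linear fold beyond `min_fold` (strict); 1.5 is the customary milder fold cutoff |
| `pool_p_min`, `pool_fold_low/high` | 0.1, 0.80–1.25 | background pool criteria (`p_adj` above, fold within, bounds inclusive) |
| `n_resamples` | 1000 | background groups per run; the attainable p floor is `1/(n_resamples+1)` |
| `frequency` | `"promoter"` | presence fraction vs `"window"` hit rate |
| `both_strands` | `TRUE` | scan the reverse strand (promoter TFBS practice; E-boxes are near-palindromic) |
| `pseudocount` | `0.25 * sqrt(N)` | log-odds smoothing, `N` = mean column depth; a common library convention |
| `kappa` | 0.2 | Hartung regularisation |
| `seed` | required in the CLI | every random draw in a run derives from it |

## Numerical and design choices

* Coordinates are 0-based half-open internally; BED output follows BED;
  1-based TSS input is accepted via `tss_base = "one"`.
* Foreground fold bounds are strict inequalities, pool bounds inclusive,
  mirroring the "above/below" vs "within the range" phrasing of the
  selection rules.
* Alternative transcripts are collapsed by keeping the first TSS per
  gene id; out-of-bounds windows are dropped with a warning rather than
  truncated, keeping all promoters the same width.
* Overlapping hits all count; there is no greedy masking.
* All tie-breaks (threshold ties, rank ties) are deterministic, and a
  run manifest (input digests, parameters, output digests) makes reruns
  verifiable byte-for-byte.
* Exact sorting of pooled scores is used for calibration — universes of
  tens of thousands of promoters are well within desk scale, so no
  approximation is warranted.

## Problem sizes used in the tests

The test suite and the acceptance script run entirely on synthetic data:
unit tests use 50–300 promoters of 100–1000 bp; the type-I-error study
uses 50 decoy motifs against a 520-gene universe of 2001-bp promoters
with 200 resamples and an independent foreground draw per decoy (the
binomial yardstick for the observed false-positive fraction assumes
independent tests); the power study plants one motif in 12 of 20
foreground promoters (60%) over the same universe with a 500-gene pool,
500 resamples, and 20 decoys standing in for the rest of a motif
collection. These sizes were chosen as the smallest at which the
studied effects are unambiguous.

## Known limitations

* The mononucleotide, GC-neutral background of the generator (above).
* The per-window ERR denominator is a declared reading of "probability
  of site prediction"; the per-promoter alternative changes the meaning
  of the grid (rates of 5e-4 per promoter would make background hits
  essentially absent and the test degenerate at small n), so it is
  offered only as an explicit sensitivity switch, not a default.
* Column permutation is a weak null for motifs sharing a column
  multiset; similarity p-values are best read as "cannot be told apart",
  not as alignment quality.
* Family labels for TFs are user-supplied annotations; the package does
  not curate motif-family databases.
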