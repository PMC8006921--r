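---
title: "Deriving core differential-expression signatures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving core differential-expression signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coresig)
```

# The problem

Case/control transcriptome comparisons — for example bronchial epithelium
from severe asthmatics against healthy volunteers — typically yield long,
noisy lists of differentially expressed genes (DEGs). A robust way to
shorten such a list is to ask, for each gene, *how many* independently
significant pathways its differential expression helps drive, and to keep
only the genes that drive more pathways than is typical. `coresig`
implements that procedure end to end: a probe filtering cascade, a
two-stage gene-set enrichment analysis (GSEA), gene-level direction calls
at a fixed score cutoff, and median-threshold selection of the "core"
genes. A synthetic-data generator with planted ground truth makes every
stage testable without any external download.

# The filtering cascade

Three per-probe predicates are applied in a fixed order; because each is
independent, the result equals the intersection of the three stand-alone
keep-sets (a property the test suite asserts).

1. **Presence floor.** A probe is kept only if its linear-scale
   ("presence", MAS5-role) intensity is at least 50 in *every* sample —
   boundary inclusive. This removes probes that are effectively absent.
2. **Coefficient of variation.** On the log-scale ("variance",
   gcRMA-role) matrix, probes with CV = sd/mean below 10% are considered
   invariant and dropped (sample sd, n − 1). The inverse ratio mean/sd
   appears in some descriptions of this filter; it is available via
   `convention = "mean_over_sd"`, but a 10% threshold is only meaningful
   under sd/mean, which is therefore the default. CV may alternatively be
   computed per group (`scope = "per_group"`, keeping probes variant in at
   least one group); the default uses all samples.
3. **Sex association.** Probes whose log-scale values differ between male
   and female samples (two-sided Welch t-test pooled across groups,
   p < 0.05) are removed, so sex-linked expression cannot masquerade as
   disease signal. No test is canonical for this step; Welch's t at
   α = 0.05 is the least-assumption two-group default, and both the test
   threshold and the skip behaviour (fewer than two samples per sex skips
   the stage loudly) are reported in the `filter_report`.

# Signal-to-noise ranking

For gene $g$ with case/control means $\mu_1, \mu_2$ and sample standard
deviations $\sigma_1, \sigma_2$ (log-scale matrix),

$$S2N_g = \frac{\mu_1 - \mu_2}{\sigma_1 + \sigma_2}.$$

Probes are first collapsed to one row per symbol by the max-mean rule (the
probe with the highest mean presence-scale intensity represents the
symbol; symbols match case-insensitively, unannotated probes are dropped
with a count). Ranking ties are broken lexicographically by symbol so
results are identical across platforms.

`sigma_floor = "gsea_default"` reproduces the desktop GSEA heuristic
$\sigma \mapsto \max(\sigma, 0.2\,|\mu|)$. The package default is
`"none"`: that floor was designed for linear-scale data where near-zero
means produce unstable ratios, but on log2 matrices with means around 10
it inflates the denominator roughly twofold for every gene and detaches
the ±0.25 classification cutoff (below) from the data scale. After the
presence filter all retained probes are well expressed and their variance
estimates are stable, so no floor is needed.

# The enrichment score and its permutation test

For a ranked list of $N$ genes and a set with $N_H$ members present,
walking down the list accumulates
$+|s_i|^p / N_R$ at hits ($N_R = \sum_{hits} |s_i|^p$, default $p = 1$)
and $-1/(N - N_H)$ at misses; the enrichment score (ES) is the running
sum's value of maximal absolute deviation, signed, hence bounded in
$[-1, 1]$. If every hit has score zero the hits weight uniformly
($1/N_H$). The leading edge is the hit prefix up to the peak (suffix from
the peak, for negative ES) — the genes that actually carry the
enrichment.

Significance uses phenotype permutation: group labels are permuted
`n_perm` times under a fixed seed, the full ranking and ES are recomputed
per permutation, and the nominal p-value is sign-stratified with add-one
smoothing,

$$p = \frac{1 + \#\{b : \mathrm{sign}(ES_b) = \mathrm{sign}(ES),\ |ES_b| \ge |ES|\}}
          {1 + \#\{b : \mathrm{sign}(ES_b) = \mathrm{sign}(ES)\}},$$

so p is never zero and ties count as extreme (conservative). Cohorts with
fewer distinct relabellings than `n_perm` are enumerated exhaustively and
flagged. Gene-set permutation is deliberately not offered as a default:
phenotype permutation preserves gene–gene correlation, which is the null
that matters here.

**Two-stage screen.** Every set is first evaluated in *absolute* mode
(ranking by $|S2N|$), which is sensitive to sets whose members move in
either direction; sets passing nominal p < α (default 0.05) are then
re-evaluated in *classical* signed mode, and a set is *significant* only
if it clears α in both stages. Both stages share one seeded permutation
block. Whether absolute enrichment ranks by $|metric|$ or by a squared
metric varies between implementations; $|metric|$ is used here.

# From significant sets to the core signature

Genes are classified **up** when $S2N \ge +0.25$ (boundary inclusive),
**down** when $S2N \le -0.25$, neutral otherwise; the literal phrasing of
this cutoff pair in some sources ("≥ 0.25 up, ≤ 0.25 down") is
self-contradictory at 0.25, and the symmetric ±0.25 reading is used.
Non-neutral genes are the *candidates*.

Each candidate is counted into the significant sets it is enriched in. By
default (`count_mode = "leading_edge"`) a gene counts for a set when it
belongs to that set's classical-run leading edge — the genes identified
as up- or down-regulated *in* that pathway; plain membership counting
(`"membership"`) is available. Leading-edge counting is both closer to
what "genes enriched in a pathway" means operationally in GSEA and much
more discriminative: a background gene that merely happens to sit in an
enriched set's membership does not collect counts.

The signature keeps the candidates whose count *strictly exceeds* the
median candidate count (even-length medians average the middle pair). The
median may instead be taken over all genes (`median_universe = "all"`).
Strict inequality means an all-equal count profile selects nothing.

`intersect_deg()` supports the follow-up step of intersecting DEG calls
across datasets or libraries, requiring direction consistency (a gene up
in one collection and down in another is reported as a conflict, not
shared). For the signature heat map, `cosine_hclust()` clusters samples
or genes under the distance $1 - \cos(x, y)$; no linkage is canonical for
this display, so average linkage is the (configurable) default, and
`dendrogram_newick()` exports the tree.

# The synthetic-data generator

`simulate_expression()` draws
$\log_2 x_{gs} = \mu_g + \delta_g\,[s \in \text{case}] +
\varsigma_g\,[s\ \text{male}] + \varepsilon_{gs}$, with
$\varepsilon \sim N(0, \texttt{noise\_sd})$, and emits the paired
matrices (presence = $2^{\log_2 x}$, variance = its log2) that emulate
the linear/log normalization pair real pipelines consume. A log2-normal
model is the natural choice because both normalization scales in scope
are log-scale methods. Sex alternates male/female within each group so
sex-filter tests are reproducible, and each artifact (expression, gene
sets, Ct tables) has its own seed stream derived from the master seed.

Defaults are the study conditions the package is validated under: 2,000
probes, 15 vs 15 samples, 30 + 30 planted genes at log2 effect 2.0 over
noise sd 1.0, 20 sex genes at log2 shift 2.0, 5% absent probes, and 100
sets of 25 genes with half planted at 60% overlap. The unstated baseline
was chosen once for realism under those conditions: expressed probes at
$\mu_g \sim N(10.5, 0.5)$ keep both filters meaningful — a floor of 50
($\log_2 \approx 5.6$) is clearly below the expressed regime yet reachable
by down-shifted planted genes' case samples, while CV ≈ noise/mean ≈ 0.1
puts genuinely invariant probes at the 10% threshold. Absent probes are
drawn around $\log_2 \approx 4$ and rescaled where necessary so every
value is strictly below 50. Planted set members are dealt round-robin
over shuffled passes of the planted pool, so every planted gene lands in
an essentially equal number of planted sets — the structure the
median-count selection is meant to detect.

What the generator does *not* emulate: probe-level chemistry, batch
effects, correlated gene modules, paired designs, or heavy-tailed noise.
Passing recovery tests on these simulations therefore demonstrates that
the machinery is correct and calibrated, not that the thresholds are
optimal for any particular real dataset.

# Assay quantifications

* **ΔΔCt.** Per sample, $\Delta Ct = Ct_{gene} - \overline{Ct}_{HK}$
  (arithmetic mean of housekeeping Cts; geometric available); the group
  contrast is the mean of per-sample ΔCts (not the ΔCt of means), and
  $RQ = 2^{-\Delta\Delta Ct}$. Undetermined target Cts are imputed to 35
  cycles (the profiler-array convention) and flagged; a sample with an
  undetermined housekeeping Ct is excluded with a warning. Swapping the
  groups inverts RQ exactly, and adding a constant to every Ct of a
  sample cancels — both are tested properties.
* **Fura-2 ratio.** $F340/F380$ per timepoint (non-positive denominators
  masked), with baseline mean over a pre-stimulus window (default: the
  first 20% of the trace), peak, and peak-minus-baseline amplitude.
* **CTCF.** $\mathrm{CTCF} = \text{integrated density} - \text{area}
  \times \text{mean background}$, the standard imaging correction; the
  quantity's name does not pin down a formula, so this choice is
  documented here. Negative values are reported as-is and flagged.

# Numerical and reproducibility choices

* Permutation scores for all label assignments are computed by matrix
  products (group sums and sums of squares against an indicator matrix),
  and per-set scores across permutations use the running sum's piecewise
  linearity: extrema can only occur at hit positions, so only $2 N_H$
  candidates per permutation are evaluated. A brute-force full running
  sum serves as the independent oracle in the tests (agreement to
  1e−12 over random instances).
* All tie-breaks are deterministic (lexicographic symbols in rankings,
  first occurrence in running-sum extrema), and every random draw flows
  from an explicit seed, so two runs with the same seed produce
  byte-identical output files.
* Degenerate inputs are defined, not crashed on: zero pooled sd gives
  score 0 with a warning; a set with no genes in the ranked list is
  flagged `no_hits` and excluded from counting; an empty candidate list
  yields an empty signature with an undefined median, flagged.
* Validation problem sizes (2,000 × 30 expression matrices, 100–200
  sets, 1,000 permutations, five replicate studies) keep a full
  validation run in the order of seconds on one CPU while leaving
  Monte-Carlo error well inside the asserted bands.

# Known limitations

* No FDR q-values or normalized enrichment scores: the procedure gates on
  nominal p-values only, as specified; multiple-testing behaviour across
  sets is therefore the user's responsibility.
* The sex filter tests mean differences; a pure variance difference
  between sexes would pass it.
* Leading-edge counting depends on the classical-stage ES peak, which can
  move under small data perturbations for weakly enriched sets; the
  median threshold downstream absorbs most of that instability.
* GCT support is deliberately limited to the #1.2 dialect.
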