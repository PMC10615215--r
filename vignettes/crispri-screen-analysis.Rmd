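---
title: "Fitness scoring for pooled CRISPRi competition screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitness scoring for pooled CRISPRi competition screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprifit)
```

## The measurement

A pooled CRISPRi screen competes thousands of knockdown mutants — each cell
carrying a single guide RNA that blocks transcription of one target — in a
shared turbidostat culture. Because the culture is held at constant density,
the pool grows exponentially and generations accumulate linearly, so a
mutant whose repressed gene matters for growth is diluted out at a rate set
by its growth defect. Sequencing the sgRNA cassettes at generations 0, 4, 8
and 10 gives per-guide abundance trajectories; the analysis problem is to
turn those into per-gene, per-condition fitness scores with calibrated
significance, and then to learn what guide sequence features predict strong
repression.

`crisprifit` implements that analysis end to end: rule-based library design,
a synthetic competition generator used for validation, count normalization,
AUC fitness scores, weighted gene-level aggregation, hit calling, and a
guide-efficacy classifier harness. The numbered scripts under `analysis/`
run these stages as a narrative workflow; all computation lives in the
package functions so the test suite exercises exactly what the scripts run.

## Guide-level fitness

For guide $i$ in one condition, let $\mathrm{lfc}_i(t)$ be its
$\log_2$ fold change versus the condition's generation-0 sample. The
fitness score is

$$F_i = \mathrm{AUC}\big(t, \mathrm{lfc}_i\big)\cdot\frac{2}{\max t},$$

with the area under the curve taken by the trapezoidal rule. The scaling is
chosen so that a linear trajectory scores exactly its endpoint $\log_2$
fold change: a mutant that loses one doubling per generation has
$F = -\max t \cdot$ slope $= $ endpoint. Because the trapezoid rule is exact
for piecewise-linear integrands this identity holds on any time grid, which
is the package's main internal consistency check. Integrating the whole
trajectory (rather than reading off the endpoint) damps the influence of a
noisy final time point.

Replicates are scored separately and averaged; whether to average
trajectories first or scores first is not determined by the formula, and
scoring-then-averaging was chosen because it is linear in the data and keeps
replicate trajectories independent.

Log2 fold changes are computed with an explicit estimator,
$\log_2\!\frac{c_{ij}/s_j + pc}{c_{i0}/s_0 + pc}$, with median-of-ratios
size factors $s_j$ and pseudocount $pc = 0.5$ (in normalized counts). This
is deliberately simpler than a shrinkage-based differential-abundance fit:
it is deterministic, fully specified, and unbiased for well-covered guides;
guides near zero counts are stabilized by the pseudocount instead of
shrinkage. The generation-0 reference is replicate-matched when replicate
labels align, otherwise the pooled mean of the generation-0 samples.

Between conditions, fold changes are quantile-normalized (the classic
sort/mean scheme, ties averaged, via limma's `normalizeBetweenArrays`) so
that conditions reaching different effective generation counts contribute
comparable score distributions. Whether normalization should span all
samples or only condition summaries is a configuration choice
(`quantile_normalize(x, columns = ...)`); the default normalizes all
post-reference samples jointly.

## Gene-level aggregation

Guides differ in repression efficacy, so gene fitness is a weighted mean:

$$F_\mathrm{wmean} = \frac{\sum_i F_i w_i}{n}, \qquad w_i = R_i E_i,$$

where $E_i = |F_i| / \max_j |F_j|$ is the guide's efficacy relative to the
strongest guide of the same target (so $E \in [0,1]$, one guide attains 1
unless all scores are zero), and $R_i$ is the Pearson correlation of guide
$i$'s cross-condition fitness profile with the mean profile of its sibling
guides, rescaled from $[-1, 1]$ to $[0, 1]$ by $(R+1)/2$. Three conventions
here are genuinely open and are fixed as follows:

* **Absolute values in $E$.** Fitness is signed, but efficacy is defined on
  $[0,1]$ with the strongest *effect* set to 1, so $|F|$ is used.
* **Leave-one-out correlation.** $R_i$ could be a pairwise average or a
  correlation with the mean of the others; the leave-one-out-mean form is
  used because it is well defined down to two guides and less noisy than
  pairwise averages. Singleton targets get $R_\mathrm{scaled} = 1$,
  zero-variance profiles 0.5 (the midpoint, i.e. no information).
* **Division by $n$, not $\sum w$.** The published form of the weighted
  mean divides by the guide count. That makes $F_\mathrm{wmean}$ a
  *shrinkage* estimator — genes with weak or discordant guides are pulled
  toward 0 — rather than a weighted average; deviating silently would make
  scores irreproducible against published tables, so the `printed` mode is
  the default and a `normalized` mode (divide by $\sum w$) is available in
  `gene_fitness()`.

For the weights (and ML labels), each guide's efficacy is taken from the
condition where its target shows the largest $|F|$ — the condition with the
most signal, hence the most informative efficacy estimate. Per-condition
weighting is available (`efficacy_pooling = "per_condition"`).

## Significance

Each target's guide scores are compared with the 10 non-targeting control
guides by a two-sided Wilcoxon rank-sum test (exact when group sizes are
small and untied; normal approximation with tie correction otherwise). When
a library carries more than 10 controls, the first 10 by id sort are used so
the test geometry (n = 1..5 vs 10) stays fixed. P-values are
Benjamini–Hochberg adjusted per condition, and effect size and significance
combine into

$$S = |F_\mathrm{wmean}| \cdot (-\log_{10} p_\mathrm{adj}),$$

with $S \ge 4$ (e.g. $|F| = 2$ at $p_\mathrm{adj} = 0.01$) called
significant. A $p_\mathrm{adj}$ of exactly 0 cannot occur from the Wilcoxon
test, but the score caps p at $10^{-300}$ defensively. All-tied inputs
return $p = 1$ flagged `tied`; a target with untestable p serializes as
`NA`, distinguishing "untested" from "tested, null".

Downstream summaries are deliberately plain: `class_summary()` counts
targets reaching $S \ge$ threshold in at least one condition per class
(percent rounded to 2 decimals); `condition_regression()` decomposes each
target's fitness profile over the cultivation variables (CO2 binary, light
as numeric photon flux, treatments as indicators — the natural coding of
the design table) by OLS, erroring with the aliased terms when the design is
rank-deficient; `paired_fitness_correlation()` and
`pathway_median_fitness()` are the matched-correlation and group-median
utilities used for, e.g., gene-versus-antisense-RNA comparisons.

## Library design rules

The designer scans the coding strand of each target for
5'-CCN-(N18..23)-3' — a protospacer with an NGG PAM on the template strand,
the orientation that blocks elongation — and applies, in order:

1. **Composition filters**: GC in [0.40, 0.80]; no $\ge 6$ consecutive G or
   $\ge 4$ consecutive T; spacer length 18–23 nt; the PAM-proximal 5-mer
   must not be on the bad-seed blocklist. The blocklist ships as a small
   default set of toxicity-associated seeds and is fully configurable —
   the filter, not the particular list, is the contract.
2. **Off-target screen**: a candidate is rejected if the 15 nt adjacent to
   its PAM occur, with at most 1 mismatch, next to an NGG *or* NAG PAM
   anywhere in the genome on either strand. The intended site is excluded
   by coordinate identity, not sequence, so duplicated loci flag each
   other. Sequences are treated as linear by default with a `circular`
   flag for wrap-around scanning.
3. **Per-site length choice**: when several lengths pass at one CCN site,
   the one closest to the canonical 20 nt is kept (ties toward shorter).
4. **Spacing selection**: up to 5 guides are picked greedily by increasing
   distance to the annotated start, skipping candidates within 5 bp of an
   already-selected guide; `position_index` 1..5 records proximity (1 =
   closest to the promoter).

The filter order (composition, then off-target, then spacing) and the
promoter-proximal greedy rule are decisions, not forced by the rules
themselves; proximity is preferred because repression efficacy declines
with distance from the start. The whole designer is validated against an
independent brute-force implementation (every substring, every position and
strand) on random 20-kb genomes.

## What the simulator emulates — and what it does not

`simulate_library()` / `simulate_counts()` generate the study conditions the
pipeline is validated under: up to 5 guides per target plus 10 non-targeting
controls; guide efficacy medians declining with position index from 0.68
(position 1) to 0.47 (position 5) with Gaussian jitter (SD 0.15, clamped to
[0.05, 1]); gene fitness from a mixture (70% neutral at 0, 25% deleterious
uniform on [-4, -1], 5% beneficial on [1, 2]); a per-(target, condition)
lognormal scaling (SD 0.25) so targets have informative cross-condition
profiles; generations 0/4/8/10; 4 replicates (the upper of the two replicate
counts such screens typically report; 3 is a config change); 4 conditions by
default — enough to make cross-condition guide correlations informative
while keeping runs fast, with an 11-condition layout being a single config
change; and multinomial sequencing at 1e6 reads per sample.

Abundance follows $p_i(g) \propto p_i(0)\,2^{s_i g/G}$ with $G$ the final
generation, so a mutant's endpoint log2FC versus controls equals its
realized fitness $s_i = f_{g,c}\,e_i$ *by construction* — simulated truth is
directly comparable to estimated $F$. An analytic mode returns expected
counts without sampling, making the full pipeline deterministic; on analytic
data the pipeline recovers $s_i$ to $10^{-9}$ up to the common
pool-renormalization term, and with sampling at the default depth the
recovery correlation exceeds 0.95.

Not emulated: sequencing overdispersion beyond multinomial (real libraries
show extra-Poisson noise; a Dirichlet-multinomial switch would tighten this
but no noise model is published for this assay), PCR jackpotting,
cross-feeding between mutants, polar effects of repression on neighboring
genes, and any mechanistic light/CO2 growth model. Passing tests therefore
demonstrate correctness of the *estimators* under a clean competition
model, not robustness to every artifact of real screens.

## Guide-efficacy learning

Guides of targets with $\max_c |F_\mathrm{wmean}| \ge 1$ (a permissive
cutoff that keeps the training set large) are labeled `low` ($E < 0.5$) or
`high` ($E \ge 0.5$; the boundary maps to high per the stated interval) and
represented by a fixed 40-nt window: the spacer plus genomic flanks trimmed
so the two sides differ by at most 1 nt (5' side gets the extra base). The
window one-hot encodes to $4 \times 40 = 160$ features named by PAM-relative
position (−1 adjacent to the PAM, positive on the PAM side); whole-guide
extras (GC, melting temperature by the Wallace rule $2(A{+}T)+4(G{+}C)$,
length, distance to promoter, and an optional precomputed
hybridization-energy score that is accepted as a column but never computed)
can be appended. A seeded 75/25 split (6,306 observations split to 4,730 /
1,576) feeds four models: random forest, depth-1 gradient boosting
(xgboost), an RBF-kernel SVM, and a small single-hidden-layer neural
network (`nnet`; the harness's "mlp" — a deliberately compact stand-in for
larger multilayer topologies, since the harness's purpose is feature
analysis, not a pretrained predictor). Defaults are single fits at sensible
grid points; hyperparameters are exposed rather than grid-searched by
default to keep runs fast and deterministic.

Interpretation uses two routes that must agree on planted signals:
tree-ensemble feature importance mapped back to the (position, base) grid
(normalized to sum to 1), and signed logo weights
$\log_2\frac{f_\mathrm{class}+\epsilon}{f_\mathrm{background}+\epsilon}$
per position and base ($\epsilon = 0.01$ smoothing; a base fixed in the
class against a uniform background weighs $\approx 2$ bits). The test suite
plants "G at position −5 implies high" and requires both routes to put that
cell on top.

## Numerical and edge-case conventions

* Coordinates are 1-based inclusive; `distance_to_start` is 0-based.
* Spacers are stored 5'→3' with the PAM-proximal base last; the bad-seed
  window is the spacer's last 5 nt, the off-target seed its last 15 nt.
* Pseudocount 0.5 on normalized counts keeps zero counts finite.
* Size factors fall back to per-sample positive subsets (with a warning)
  when no guide is positive everywhere.
* `quantile_normalize` on a single column warns and returns the input.
* All-zero fitness in a target gives $E = 0$ for every guide; `max(E) = 1`
  is guaranteed whenever any guide has nonzero fitness.
* Randomness is seeded everywhere; `run_pipeline()` derives per-stage seeds
  from the global seed by a fixed hash so toggling one stage never shifts
  another's stream, and reruns are byte-identical.

## Problem sizes used in validation

The shipped tests run a 500-target × 5-guide screen (10 controls, 4
conditions, 4 replicates, depth $10^6$) for parameter recovery, random
20-kb genomes for designer-oracle equivalence, full enumeration for all
Wilcoxon group sizes with $n+m \le 12$, and 1,200 random windows for
planted-motif recovery — sizes chosen to make the statistical checks sharp
while keeping a full test run in minutes on one core. The `analysis/`
scripts use a 300-target screen for the same reason.

## Limitations

Scores inherit the assay's confounders: incomplete repression leaves
residual enzyme capacity, so a mild score does not prove a gene is
dispensable; repression of overlapping features (antisense RNAs, internal
TSS) partly measures the host gene; and the weighted mean's division by
$n$ means single-guide targets with modest weights are biased toward 0 by
design. The efficacy classifier is a harness for sequence-feature analysis;
its absolute accuracy on real screens is limited by label noise in $E$ and
by features the window representation cannot see.

## A short worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_targets = 100, seed = 7)
sim <- simulate_library(cfg)
cm  <- simulate_counts(sim$library, sim$truth, cfg)
l2  <- quantile_normalize(log2fc(cm))
ft  <- compute_fitness_table(fitness_scores(l2), sim$library)
head(ft$target[order(-ft$target$S), ])
```
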