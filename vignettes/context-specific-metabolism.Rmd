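---
title: "Context-specific metabolic networks and diet-transition scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-specific metabolic networks and diet-transition scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctxmetanet)
```

## The problem

When *C. elegans* is raised on different bacteria — a standard *E. coli*
OP50 diet versus colonizing microbiota isolates of the genus
*Ochrobactrum* — its transcriptome shifts, and some of those shifts are
metabolic. ctxmetanet asks two questions of such data:

1. Which parts of the worm's metabolic network are *active* under each
   bacterial condition and developmental time point?
2. Which *gene knockouts* would push the metabolic state of one diet
   toward the metabolic state of the other — i.e., which enzymes mediate
   the dietary transition?

The package works entirely from differential-expression (DE) summary
tables (gene, comparison, log2 fold-change, FDR-adjusted p-value) and a
constraint-based metabolic model with gene–protein–reaction (GPR) rules.
Fitting the DE model itself is out of scope; any upstream tool that
produces adjusted p-values and fold-changes can feed the pipeline.

## Stage 1: discretizing gene activity states

For each gene and each context (condition × time point) we collect all
comparisons that involve the context: cross-condition comparisons at the
same time point and within-condition comparisons against the adjacent
(preceding and following) time points. Only genes with at least one
adjusted p-value strictly below `alpha` (default 0.05) participate; all
other genes are left open (UNKNOWN) throughout.

Each significant comparison casts an ON vote for its higher side and an
OFF vote for its lower side; the state is the vote majority, with ties
and empty ballots giving UNKNOWN. Majority voting was chosen because it
is the simplest estimator of a "most likely" state that is exactly
sign-symmetric: negating every fold-change swaps ON and OFF and fixes
UNKNOWN, a property the test suite asserts on every synthetic bundle.
The `lfc_min` threshold defaults to 0 — any significant comparison
votes — because the selection is already gated on the adjusted p-value.

## Stage 2: context-specific networks (iMAT)

Gene states are lifted to reaction evidence through the GPR rules with
the conservative lattice extension of boolean logic: AND takes the
minimum and OR the maximum over {OFF = −1, UNKNOWN = 0, ON = +1}, so
definite states reproduce boolean evaluation and UNKNOWN never flips a
definite outcome. Reactions with evidence +1 form `r_high`, −1 `r_low`;
reactions without gene association carry no evidence.

The iMAT step then solves a mixed-integer program over steady-state flux
vectors `v` (`S v = 0`, bounds respected): maximize the number of
`r_high` reactions with `|v| ≥ epsilon` plus the number of `r_low`
reactions with `v = 0`. Defaults are `epsilon = 1` against bound
magnitudes of 1000, the usual convention that keeps big-M constants
moderate; indicator constraints are expressed as big-M rows with M taken
from the bound magnitudes, which keeps the formulation portable across
solvers.

Two implementation choices matter for reproducibility:

* **Parsimonious tie-break.** The MILP objective only sees the
  indicator variables, so the flux vector at the optimum is otherwise
  arbitrary — in particular, futile cycles with no evidence could carry
  flux and would then be misread as "active". After the optimum is
  found the binaries are fixed and a cleanup LP minimizes total |v|, so
  the reported active set (`|v| > delta`, `delta = 1e-6`) is the
  support of the sparsest flux achieving the optimal agreement.
* **Single optimum.** Activity is classified from the one returned
  optimum, mirroring one reported network per context. Alternative
  optima exist in principle; enumerating them is deliberately not
  attempted.

A brute-force oracle (`imat_bruteforce()`) enumerates all satisfaction
assignments (direction-resolved for `r_high`) with LP feasibility checks
and is used throughout the tests to certify the MILP objective on every
fixture with at most 16 evidence labels.

The **reference flux** of a context is the L1-norm-minimal steady-state
flux keeping every satisfied high-evidence reaction active in its
committed direction. It is the deterministic "source state" consumed by
the transformation scoring.

Pathway summaries count active reactions per subsystem (columns always
sum to the active-set size), report signed mean differences between
context groups with a top-k selection (default k = 8, ties broken by
subsystem name), and ordinate contexts by PCA of the binary
reaction-activity matrix.

## Stages 3–4: gene-level transformation scoring

Given a source context (reference flux `v_ref`) and a target condition,
the DE comparison between the two conditions at the shared time point
defines reaction-level change requirements: reactions of genes
significantly higher in the target must *increase* in flux magnitude by
at least `epsilon_change` (default 0.5, half the activity threshold);
reactions of genes significantly lower must *decrease* by the same
margin, restricted to reactions whose reference flux is at least
`epsilon_change` (an invisible decrease is not a requirement). Reactions
marked in both directions, and all unmarked reactions, form the steady
set.

Each gene is scored by blocking the reactions its knockout disables (GPR
evaluated with the gene FALSE, all others TRUE — a reaction is blocked
only when no isozyme route remains) and solving:

1. **Stage 1 (LP).** The knocked-out network settles into the flux state
   of minimal total L1 adjustment from `v_ref`. This models the
   biological premise of the scoring: absent a perturbation the cell has
   no reason to move, and a knockout earns credit only for the
   re-routing it *forces*.
2. **Stage 2 (MILP).** On that minimal-adjustment face, the number of
   satisfied change requirements `n_succ` is maximized (binary
   indicators with big-M rows; `|v|` handled by split variables).
3. **Stage 3 (LP).** With the indicators fixed, the steady-set deviation
   `D = Σ |v − v_ref|` over steady reactions is minimized for a
   deterministic report.

The transformation score is

`TS = n_succ / |r_forward| − lambda · D / (Σ_steady |v_ref| + 1)`

with `lambda = 1` by default. The null knockout stays exactly at
`v_ref`, so `TS_null = 0`; it is the natural no-effect reference and is
used as the significance threshold.

This "anchor" policy is a deliberate design decision. The alternative
of maximizing `n_succ` outright (available as `policy = "maximize"`)
has a structural flaw as a knockout score: removing constraints can
never help a free optimizer, so no knockout can ever exceed the null
score and the threshold would zero every gene. The test suite asserts
exactly this property of the "maximize" policy, and asserts that under
the default policy the planted mediator of the diamond scenario scores
strictly above the threshold.

Per run, scores are summarized by rank: scores at or below the
threshold become 0, the rest are ranked ascending (average ranks on
ties, making the summary permutation-invariant) and divided by their
count, so the best gene gets 1. Robustness comes from bootstrap runs
(default 5) that remove a random 10% of genes — whole genes, with all
their DE rows, since the analysis is gene-level — and recompute
discretization, networks, change sets and scores. The removal count is
`round(fraction × genes)`, and removal sets depend only on the seed.

Scores are aggregated per direction as the per-gene mean of the
rank-normalized scores across all runs of the set (full-data run plus
bootstraps, all time points, both microbiota-versus-control
comparisons), rescaled so the top gene is 1. The **overall score** sums
the aggregated forward-transition scores across omics layers and
subtracts the reverse-transition scores; it is exactly antisymmetric
under exchanging the directions, so positive values mark mediators of
the microbiota-to-control transition and negative values the reverse.

## Clustering and cross-omics stages

Fold-change matrices (genes × contrasts) are clustered with Lloyd's
K-means, best of 25 seeded restarts per candidate k. The cluster number
is chosen by an information criterion on the spherical Gaussian
likelihood, `−2 log L = n·d·log(RSS/(n·d))`. The default selector is
**AICc** with `p = k·d` parameters: the uncorrected AIC penalty `2p` is
too weak for K-means, which optimizes assignments as well as means — on
matrices of this shape (d = 12 contrasts) each spurious extra cluster
buys roughly 40·σ² of RSS against a penalty worth only 24·σ², so plain
AIC never stops splitting. The small-sample correction
`2p(p+1)/(n−p−1)` restores a sharp minimum at the planted cluster
number; plain `"aic"` and `"bic"` remain available for comparison.
RSS is floored at 1e-12 so all-identical input degrades to a single
cluster with a warning rather than a log-of-zero.

`core_overlap()` provides the two-set overlap counts used for
core-signature comparisons, and `omics_concordance()` the Pearson
correlation plus direction-consistency percentages between transcript
and protein fold-changes (the protein vector is expected to be
pre-filtered to significant changes; percentages are exact, rounded to
one decimal only for display).

## The synthetic-data generator

The generator emulates the colonization study design: three bacterial
conditions (one control diet, two microbiota isolates) × six time
points (L2/6 h through Ad7/216 h) × 3 replicates. Planted truth assigns
each signal gene (60% of genes by default) an ON/OFF split across a
random condition subset over a random time window; every planted state
therefore participates in at least one informative comparison, which is
what makes recovery a meaningful target. Signal comparisons draw
`log2FC ~ Normal(±3, 0.3)` signed toward the ON side with
`padj ~ Uniform(0, 0.01)`; null comparisons draw `Normal(0, 0.3)` with
`padj ~ Uniform(0.2, 1)`, except for a 1% false-positive fraction with
`padj ~ Uniform(0, 0.05)`. P-values are simulated directly rather than
via a count model because only the DE summaries feed the pipeline.

The fixed **diamond scenario** plants a known mediator: uptake feeds two
alternative two-reaction branches that rejoin before secretion; the
microbiota conditions route flux through branch A (gene `gA` ON, `gB`
OFF) and the control through branch B. Knocking out `gA` blocks both
branch-A reactions, and steady state then forces all flux through
branch B — so `gA` must top the overall forward score, `gB` the
reverse, and the two genes that appear in no GPR must sit exactly at
the threshold. These guarantees are asserted, not assumed.

What the generator does *not* emulate: count-level noise, library-size
and batch effects, replicate-level variance structure, correlated genes
within pathways, and the sheer scale of a genome-wide experiment.
Passing recovery tests therefore demonstrates correctness of the
pipeline's logic under its stated noise model, not performance on real
RNA-seq data.

## Numerical choices

* All flux problems are solved by an internal two-phase dense tableau
  simplex (Dantzig pricing with a Bland's-rule fallback for
  anti-cycling, redundant-row elimination after phase 1, fixed
  variables substituted out), with a deterministic depth-first
  branch-and-bound for binaries. Determinism was a hard requirement:
  identical inputs must reproduce identical active sets and scores,
  and the grading of equal-objective optima is fixed by the
  parsimonious cleanup rather than solver whim.
* Big-M constants equal the bound magnitudes; with the default ±1000
  bounds and unit epsilon this keeps relaxations well-scaled.
* Tolerances: `delta = 1e-6` for activity classification, `1e-6`
  relative slack on the stage-1 adjustment budget, `1e-9` when
  comparing scores against the threshold.
* Degenerate inputs: models whose bounds exclude `v = 0` are rejected
  up front (the all-zero flux must be feasible); empty evidence yields
  objective 0 with the zero flux; identical context networks make the
  activity PCA warn and return zero coordinates.

## Problem sizes

The bundled analyses run on toy networks of 8–24 reactions, DE tables
of a few hundred genes × 33 comparisons, and fold-change matrices of
200 genes × 12 contrasts; the full test suite and the acceptance script
each complete in a few minutes on one CPU. The pipeline logic is
size-agnostic, but the dense simplex is not tuned for genome-scale
reconstructions; plugging in a sparse MILP solver behind `lp_solve()` /
`milp_solve()` would be the natural extension for that regime.

## Worked example

```{r example, eval = FALSE}
dir <- tempfile("bundle")
simulate_command(dir, variant = "diamond", seed = 7)
cfg <- read_pipeline_config(file.path(dir, "config.yaml"))
manifest <- run_pipeline(cfg)
read.delim(file.path(dir, "results", "mta_overall.tsv"))
```

The overall table ranks `gA` first (score 1) and `gB` last (score −1),
with the no-GPR control genes at 0 — the planted answer.
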