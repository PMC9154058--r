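---
title: "Methods: classifying duplicated protein domains and measuring their divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying duplicated protein domains and measuring their divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modfree)
```

This vignette documents the models, numerical choices and design decisions
behind `modfree`, in the spirit of a methods section: what each stage
assumes, which knobs matter, and what the synthetic-data tests do and do
not establish about real data.

## The problem

Gene families that carry a repeatedly duplicated protein domain — the
motivating case is the ZP-N domain of egg-coat proteins, present both as
the "modular" copy inside the ZP-N/ZP-C polymerization module and as
free-standing N-terminal repeats — pose two linked questions:

1. Do the copies fall into distinct evolutionary classes, and which
   alignment positions (and residues) diagnose the classes?
2. How divergent are the copies within and between orthogroups (one
   orthogroup = one domain position in one paralog, followed across
   species), and which copies show evidence of positive selection?

`modfree` implements a desk-scale, fully testable pipeline for both
questions. It deliberately does not wrap external aligners, tree builders
or codon-model fitters: structure-guided alignments and site-model
log-likelihoods are inputs, produced by the specialist tools a study would
use anyway.

## Alignment preparation

**Ambiguity filtering.** Sequences are restricted to the 20 canonical
amino acids plus the gap `-`; any other symbol (X, B, Z, J, U, O, `*`)
disqualifies the whole record. `.` is rejected already at parse time: one
canonical gap dialect, with an explicit error rather than silent
translation.

**Dereplication.** `dereplicate()` is a greedy redundancy filter in the
spirit of CD-Hit: records are processed in decreasing order of ungapped
length (ties broken by id in C collation, making the result deterministic
and independent of input order), and a record is kept only if its identity
to every previously kept record is at or below the threshold (default
0.90; "above 90%" is read strictly, so records at exactly 0.90 survive).
Identity is matches over comparable positions: aligned columns with
residues in both rows when the two records share an alignment, otherwise
position-wise comparison of the gap-stripped sequences over the shorter
length. This is a documented simplification — no k-mer prefilter and no
pairwise alignment are performed, because the stage is a redundancy filter
ahead of the analysis, not a result of it.

## Representative-guided merging

Orthogroup alignments are mutually unalignable by ordinary profile methods
when sequence identity between paralogs is low; the pipeline therefore
assumes a *representative alignment* (one row per orthogroup, typically
structure-guided) and propagates its gap structure.

For each orthogroup, `build_column_map()` aligns the representative's row
in the master coordinates with the same sequence's row in the orthogroup
alignment (their ungapped content must match exactly). Local columns where
the representative carries a residue map onto the master column holding
that residue. Local columns where the representative is gapped are
*insertion columns*: content present in some group members but absent from
the representative, for which no cross-orthogroup homology statement is
possible. Design decisions, made where the procedure itself is
underdetermined:

* An insertion column is anchored to the nearest preceding
  representative-residue master column (anchor 0 = before the first) and
  placed immediately after it.
* Insertion blocks from different orthogroups sharing an anchor are laid
  out as disjoint adjacent runs in lexicographic orthogroup order. Any
  fixed order would do; lexicographic is deterministic and testable.
* Insertion columns are never re-aligned across orthogroups. Residues from
  two orthogroups in one insertion column would assert a homology the
  method never established, so rows of other orthogroups carry gaps there.

The merge preserves every row's ungapped sequence exactly, and
`strip_empty_columns()` removes columns that are gaps in every row. The
central oracle of the test suite runs the construction backwards:
`simulate_orthogroup_split()` cuts a known master into orthogroup
alignments plus a representative alignment, and merging must reproduce the
master byte-for-byte when its co-anchored insertion blocks are already in
canonical order, and up to that reordering otherwise. This holds only for
masters with the structure the merge asserts (each group's residues
confined to its representative's columns plus group-private insertions) —
which is exactly the structure real inputs produced by per-orthogroup
realignment have.

## The sparse classifier

**Encoding.** Each alignment column becomes 20 indicator features in fixed
alphabetical residue order; a gap leaves the whole block at zero. A model
over an alignment of length $L$ has $1 + 20L$ parameters including the
intercept (for the 466-column study alignment, 9,321). Features are left
as 0/1 indicators without standardization: they share a scale by
construction, so penalization is already comparable across features.

**Loss versus scoring metric.** The model is a logistic regression, and
fitting minimizes the mean logistic log-loss; the cross-validation *score*
used to compare hyperparameters is the negative mean squared error between
predicted probabilities and 0/1 labels. Fitting a probabilistic classifier
by its natural convex loss while scoring by squared error reconciles the
two descriptions of the procedure this design follows ("logistic
regression" and "mean-squared" scoring) and keeps the solver's objective
smooth and convex.

**Solver.** The penalized objective

$$
\frac{1}{n}\sum_i \left[\log(1+e^{m_i}) - y_i m_i\right]
 + \lambda\left[\alpha\lVert w\rVert_1
 + \tfrac{1-\alpha}{2}\lVert w\rVert_2^2\right],
\qquad m_i = \beta_0 + x_i^\top w,
$$

with the intercept unpenalized, is minimized by FISTA (accelerated
proximal gradient) with a function-value restart; the L1 term enters
through soft-thresholding, so eliminated coefficients are exact zeros and
`nonzero_count` is a literal count, not a threshold on small values. The
step size is $1/L_f$ with
$L_f = s_{\max}^2([1\,X])/(4n) + \lambda(1-\alpha)$ (logistic curvature is
at most 1/4; softmax at most 1/2 for the multinomial variant), where
$s_{\max}$ is obtained by power iteration and cached across a grid search.
Convergence is declared when the relative objective decrease falls below
`tol` (default $10^{-9}$ for single fits, $10^{-8}$ inside the grid);
non-convergence is flagged and warned about, never hidden. The test suite
checks the solver against a dense coarse-to-fine grid minimization on
small instances, against glmnet as an independent reference solver, and
against the elastic-net KKT conditions evaluated with numerical gradients.

**Grid search and CV.** The default grids are 10 log-spaced $\lambda$
values on $[10^{-4}, 10]$ and $\alpha \in \{0.1, 0.3, 0.5, 0.7, 0.9, 1\}$.
The smallest $\lambda$ serves as the (near-)unregularized endpoint of the
path: a literal $\lambda = 0$ fit diverges on separable data, so it is
admitted only under the iteration cap. Folds (default $k = 5$) are
stratified by class with a seeded assignment; the per-point score is the
mean across folds and its standard error is the fold standard deviation
over $\sqrt{k}$. Fits are warm-started along decreasing $\lambda$, which
cannot change the optima (the objective is strictly convex for
$\lambda(1-\alpha) > 0$ and the solver is run to tolerance) but shortens
the path. Argmax ties break toward larger $\lambda$, then larger
$\alpha$ — toward more regularization, deterministically.

**Selection rule.** `select_parsimonious()` qualifies every grid point
whose CV score is at or above the anchor's score minus
`ci_multiplier` × the anchor's standard error — 1.96 standard errors for
the 95% confidence band — and returns the fewest-nonzero-parameters
qualifier (ties: higher score, then larger $\lambda$). The band is
one-sided below the anchor, since no model can meaningfully beat the best
observed score by more than noise. Two anchors are exposed because the
source procedure is described both ways in different places: `"best"`
(the highest-scoring grid point; the default) and `"least_regularized"`
(the smallest-$\lambda$ point). The model evaluated on the held-out test
set is the selected grid point refit on the full training set, not an
average of fold models.

**Outputs.** `export_logo_weights()` tabulates the retained
(column, residue) weights — the exact per-residue log-odds contributions,
since the decision log-odds is the intercept plus the sum of matched
weights — with positive weights "modular-associated" and negative ones
"free-associated". `clade_frequency_logo()` provides the descriptive
counterpart for clade subsets: per-column residue frequencies over non-gap
rows, the gap fraction, and information content $\log_2 20 - H$ in bits
(an all-gap column is reported as gap fraction 1 with zero information).

## Divergence statistics

Pairwise distances use the proportion of differing residues $p$ over
comparable columns with *pairwise deletion* of gap positions (the
complete-deletion alternative would discard most of a merged alignment's
columns; the choice is exposed by using `p_distance` directly). Multiple
hits are corrected by Poisson correction $d = -\ln(1-p)$ or, allowing
site-to-site rate variation with gamma shape $a$, by
$d = a[(1-p)^{-1/a} - 1]$. The gamma correction dominates the Poisson
correction for every $p \in (0,1)$ and converges to it as
$a \to \infty$; both are property-tested. The shape parameter defaults to
$a = 1$ and is echoed in every result object, so no output is silently
shape-dependent. Saturated pairs ($p \ge 1$ is impossible for residue
data, but $p = 1$ occurs) are excluded from cell means and counted,
never clamped. `group_mean_distances()` assembles the symmetric
orthogroup × orthogroup matrix (diagonal = within-group means over
$n(n-1)/2$ pairs, off-diagonal over $n \cdot m$ pairs), and
`filter_species_by_presence()` implements the inclusive ≥ 10-orthogroup
species filter used upstream of such analyses.

## Selection screen

Site-model comparisons (M8 vs. M8a) are fitted by external codon-model
software; `lrt_pvalue()` consumes the log-likelihood pairs, forms
$2(\ln L_\text{alt} - \ln L_\text{null})$ clamped at zero (a negative
value can only be optimizer noise and triggers a warning), and refers it
to $\chi^2_1$ as stated for this comparison; the common 50:50 boundary
mixture of $\chi^2_0$ and $\chi^2_1$ is available behind `mixture = TRUE`
for users who prefer it. `benjamini_hochberg()` implements the step-up
rule explicitly (rejections and adjusted p-values); the test suite checks
it against brute-force enumeration of the rule and against
`stats::p.adjust`.

## The synthetic-data generators

`simulate_classed_alignment()` emulates the statistical shape the
classifier assumes: a small set of class-diagnostic columns held at fixed
residues within their class (default: 8 modular-diagnostic and 2
free-diagnostic columns, mirroring the shape of the motivating finding),
i.i.d. background draws everywhere else (uniform by default), and i.i.d.
gaps (default rate 0.05) outside diagnostic columns. Default sizes are 200
sequences per class and 100 columns. A `fidelity` below 1 degrades the
diagnostic columns gradually; `n_diagnostic = c(modular = 0, free = 0)`
gives the null generator, on which held-out accuracy must hover at chance.

`simulate_divergent_pairs()` uses the simplest substitution model with a
closed-form link between distance and expected difference: equal-input
over 20 residues. Each site draws a rate $r \sim \Gamma(a, \text{mean }1)$
shared by both lineages; each lineage accumulates
$\text{Poisson}(d/2 \cdot r)$ replacement events, each landing uniformly
on the 20 residues. Since any positive number of events leaves a uniform
end state, two endpoints differ with probability $19/20$ whenever at
least one event occurred on the path between them, giving

$$
\operatorname{E}[p] = \frac{19}{20}\left(1 - (1 + d/a)^{-a}\right)
$$

after integrating $1 - e^{-dr}$ over the gamma rates. The 19/20
visible-change factor lives in this oracle (and in the test suite's
independent Monte-Carlo reimplementation of it), deliberately not in the
estimator: the gamma-corrected estimator is applied exactly as it would be
to real data, and the recovery test asks that its mean over pairs agree
with the oracle's expectation, not with the nominal $d$.

**What passing tests do not show.** The generators draw background columns
independently across sequences and sites; real alignments carry
phylogenetic correlation, composition bias, conserved secondary-structure
blocks and indel structure, all absent here. Planted-signal recovery
therefore demonstrates that the estimator and selection rule work under
the model they assume — it does not promise that ten residues suffice on
any real family, and the specific residue identities of the motivating
study are not reproducible without its full curated alignment.

## Problem sizes and runtime choices

The suite's end-to-end checks run at the following sizes, chosen as a
balance between statistical resolution and a test suite that stays
pleasant to run:

* headline classification run: 400 sequences × 100 columns, full default
  grid (60 points × 5 folds), one seed;
* planted-column recovery: 10 seeds at 200 sequences × 60 columns, full
  default grid — every nonzero weight of every selected model must sit in
  a planted column;
* merge reconstruction: 100 random structured masters;
* divergence recovery: 50 pairs × 5,000 sites at $d = 1$, $a = 1$,
  compared to the Monte-Carlo oracle within three standard errors.

## Known limitations

* Dereplication identity is exact-position based after gap stripping for
  unaligned inputs; highly similar sequences of different lengths related
  by an indel near the start can evade it. Inputs that share an alignment
  (the intended use) are unaffected.
* The merge requires the representative's ungapped sequence to match
  between the master and orthogroup alignments exactly; trimming
  differences must be resolved upstream.
* Insertion columns are group-private by design; analyses that sum over
  columns (e.g., the classifier) see them as mostly-gap columns, which is
  intended but means insertion content contributes little signal.
* The multinomial fit uses the symmetric softmax parameterization; the
  penalty makes it identified, but per-class weights are interpretable
  only relative to the other classes.
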