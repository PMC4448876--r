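---
title: "Phylogenetically corrected disparity, diversity and rate curves: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetically corrected disparity, diversity and rate curves: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

morphodyn turns a dated, fossil-inclusive phylogeny and its discrete
morphological character matrix into three per-million-year curves:
morphological disparity, lineage diversity and absolute evolutionary
rates. This vignette records the models behind each stage, the
parameters that matter, and the numerical and design choices that were
genuinely open, so that results are interpretable without reading the
source.

## 1. The setting

The intended input is a total-evidence dated tree: extinct species are
tips placed at their (oldest) fossil occurrence ages, extant species sit
at 0 Ma, branch lengths are in Ma, and the consensus tree carries a
median relative clock rate per branch. Fossil records of this kind are
gappy in two ways — many taxa are scored for under half of the
characters, and whole intervals (e.g. a 3-Ma stage with no described
species) are empty — which biases naive, occurrence-only disparity and
diversity curves. The package therefore applies three phylogenetic
corrections before computing anything:

1. missing scorings are replaced by parsimony ancestral states when
   those are unambiguous;
2. each taxon ranges over its full dated-tree duration (its *ghost
   range*, from the origin of its terminal branch to its tip age,
   optionally extended to the age of younger referred material);
3. each internal branch joins the sample as a *hypothetical ancestor*
   (a *ghost lineage*) carrying its reconstructed states and spanning
   its branch.

## 2. Ancestral states

For one character on a rooted (possibly multifurcating) tree the package
computes the complete MPR set at every node: the set of states that
occur in at least one reconstruction of minimal total cost. Costs are
`1{a != b}` for unordered characters and `|a - b|` for ordered ones
(linear transition series). Missing and inapplicable tips carry the full
state set; polymorphic tips carry their observed set, any member
reachable at zero cost.

Rather than separate Fitch/Hartigan passes (unordered) and Farris
interval passes (ordered), both cases run through one min-cost dynamic
programme over states with an outside pass: `cost_v(s)` is the minimal
cost of the subtree below `v` given state `s`, `h_v(s)` the minimal cost
of everything outside, and the MPR set at `v` is
`argmin_s cost_v(s) + h_v(s)`. This is algebraically the same
optimisation, handles polytomies and state-set tips uniformly, and
yields MPR sets *at the tips as well* — which is exactly what tip
filling needs, since a missing tip cell's parsimony estimate is the
tip's own MPR set with that cell unknown. The test suite verifies the
implementation against exhaustive enumeration over all internal
assignments (200 random instances, up to 8 tips and 4 states, ordered
and unordered, with missing and polymorphic cells) and against an
independent Fitch implementation (phangorn) for tree lengths.

"Unambiguous" means a singleton MPR set over *all* most-parsimonious
reconstructions, not just the downpass set: a cell is filled (or an
ancestor scored) only when every minimum-length reconstruction agrees.
Observed cells, including polymorphisms, are never overwritten.
Inapplicable (`-`) scorings are treated as missing throughout the
computation but preserved distinctly on disk.

## 3. Lineage durations and the root

`lineage_durations()` emits one row per lineage: terminal branches span
`[parent age, tip age]` (extended to younger-material ages when the
diversity/disparity convention is on; never for rates), and every
internal node is a ghost lineage spanning its subtending branch. The
root has no subtending branch — any stem edge in the input file is
ignored — so it enters with a zero-length duration at the root age: it
is still an ancestor whose morphology is reconstructed, but it occupies
no time and therefore joins no bin. This convention keeps two identities
exact: the durations (without extensions) sum to the total tree length,
and the augmented sample has `n_tips + n_internal_nodes` rows (roughly
twice the taxon count on a binary tree).

## 4. Disparity

**Distances.** For rows `i, j` let `S_ij` be the characters scored in
both. The default coefficient is the rescaled ("generalized") Euclidean
distance `d_ij = sqrt((C / |S_ij|) * sum_{k in S_ij} delta_k^2)` with
`C` the total character count — the convention of the MATRIX family of
disparity tools. With complete data the factor is 1 and `d` is the
ordinary Euclidean distance on state vectors; with missing data it
prevents sparse rows from drifting towards everything else. Plain
pairwise deletion (`rescale = "raw"`) is available; at the ~7% missing
level of a phylogenetically corrected matrix the two differ little.
Polymorphic cells contribute the minimum difference over cross-set state
pairs. Row pairs sharing no scored character are flagged; more than 5%
of such pairs is an error by default.

**Ordination.** Principal coordinates analysis is classical metric
scaling: Gower double-centering of `-d^2/2` and an eigendecomposition
(delegated to `stats::cmdscale`; `ape::pcoa`, an independent
implementation, is the cross-check in the tests). Character distances
are generally non-Euclidean, so negative eigenvalues appear; they are
discarded, and percent variance is reported over the positive
eigenvalues only (no Cailliez/Lingoes correction — matching the default
behaviour of the ordination software palaeobiologists typically use).
Scores are scaled so the squared scores on axis m sum to its eigenvalue;
hence axis variances are `lambda_m / (n - 1)` and the sum of variances
over all positive axes equals `sum(lambda) / (n - 1)` exactly (a
Parseval identity the tests assert at 1e-9).

**The curve.** Default bins are half-open 1-Ma intervals
`[older, younger)` from 37 to 0 Ma. A lineage is a member of every bin
its duration overlaps with positive length — so a zero-length root
duration joins nothing, and a short-lived lineage near an edge counts
once. Per bin the statistic is the sum over the retained axes of the
score variance of the members, with the n−1 (sample) denominator; the
paper trail behind these curves does not state n vs n−1, so the
unbiased choice is the default and both the axis count (`k_axes`) and
bin membership rule are explicit arguments. Axes are retained up to 95%
cumulative variance by default (an explicit `k_axes` overrides).
Uncertainty is a percentile bootstrap: members resampled with
replacement within each bin, 1000 replicates, 95% band. Bins with fewer
than two members are *undefined*, never zero-filled. The rarefied
variant draws exactly `n_sub = 8` members without replacement per
replicate and reports the mean and percentile band, removing
sample-size differences between bins; with exactly 8 members it
degenerates to the full value.

## 5. Diversity

The LTT curve counts lineages alive at each bin-edge age. "Alive at age
a" is `end < a <= start`: a lineage exists at the age it originates but
not at the age it ends — its end is an extinction (or its last recorded
material) — except that lineages reaching 0 Ma are censored by the
present rather than dead, and so count at 0. Consequences the tests pin
down: the count at the root age equals the root degree, the count at 0
equals the number of extant tips, and with fossil tips the curve can
decline, which is the entire point of drawing it from a fossil-inclusive
tree. An overlap-mode variant (count lineages overlapping each bin) is
provided for comparability with the disparity convention.

## 6. Rates

Relative branch rates (dimensionless multipliers from a relaxed-clock
analysis, read from `[&rate=...]` Newick comments) convert to absolute
rates as `relative x clock x 100` % change/Ma; with the motivating
study's median clock of 0.0018 changes/character/Ma, a 1x branch runs at
0.18 %/Ma and a 5.5x branch at 0.99 %/Ma. The binned curve is the
*unweighted* mean over branches whose span overlaps the bin — "average
across lineages" reads as per-lineage averaging — with a duration-
weighted option; the band is ±1 SEM (`sd/sqrt(n)`), 0 for single-branch
bins. Branch spans here are the raw dated-tree durations: younger
referred material documents later survival, not later character change,
so extensions are never applied in rate mode. A midpoint-sampling mode
(branches crossing the bin midpoint) is exposed because the averaging
convention in published figures is usually unstated.

**Peaks.** `peak_age()` reports the midpoint age of the *oldest* bin
attaining the maximum: a curve that rises to a plateau is said to peak
where the plateau is first reached, which is how peak ages of
palaeodiversity curves are normally quoted, and is deterministic under
ties (integer-valued LTT curves tie often).

## 7. The synthetic world

The simulator emulates the shape of the motivating dataset so that
every stage is testable offline; its defaults are fixed and should be
read as the package's stated test world, not as tuning knobs.

| parameter | default | rationale |
|---|---|---|
| birth, death (per lineage/Ma) | 0.45, 0.37 | marine-mammal-like turnover: mean species duration ~2-3 Ma, modest net diversification |
| fossil sampling psi | 0.5 | recovers most multi-Ma extinct lineages, matching a well-sampled marine record |
| origin age | 38 Ma | the motivating clade's window |
| accepted tip range | 70-115 | keeps fixtures near the ~90-taxon shape |
| clock mean | 0.01 changes/char/Ma | the prior mean used for the study's clock |
| clock sd | 0 | the study's 0.1 was a *prior* width; drawing a generative rate from N(0.01, 0.1) would be mostly negative, so the realized clock is fixed unless `clock_sd > 0` (truncated normal) |
| igr variance | 0.1 | the default prior mean for the uncorrelated-gamma clock in the software the study used |
| characters | 272; 2-4 states (65/25/10%); 25/272 ordered | matrix shape; only >= 3-state characters are eligible to be ordered |
| gamma shape (across characters) | 0.5 | strong rate variation across characters, as model comparison favoured |
| missing fraction | 0.43 | the raw matrix's missing level; uniform deletion by default, a beta-distributed per-taxon mode emulates fragmentary fossils |
| stratigraphic window | 2 Ma | stage-level dating uncertainty |

Simplifications, all deliberate: igr multipliers are i.i.d. gamma with
mean 1 per branch (duration-independent); fossil tips arise only from
terminal extinct lineages (a sample on an internal branch would be a
sampled ancestor, which the tree model here does not represent, so such
samples are dropped); a fossil tip is dated by its *oldest* sample, and
later samples on the same pendant lineage become its younger referred
material — mirroring how fossil tips are calibrated in practice.
Ordered characters evolve by ±1 steps (a birth-death chain on states,
reflecting at the ends); unordered ones jump uniformly. Epoch
multipliers scale all characters' rates inside age windows to create
early-burst regimes; branches are split at epoch boundaries and the
per-branch duration-weighted multiplier is recorded as ground truth.

The generator records complete truth (tree ages, branch multipliers,
root states, every state change with its age and branch, the deletion
mask), and the tests replay the change history to confirm it reproduces
the emitted matrix exactly.

## 8. The recovery experiment, and what green tests mean

The end-to-end check simulates twenty ~50-tip, 100-character datasets
whose change rate is 5x between 38 and 28 Ma and 1x afterwards — the
window chosen to match the radiation phase of the motivating clade —
and asks (i) that the binned curve built from the *true* branch rates
shows the burst (early/late mean ratio > 2 in at least 16/20), (ii)
that the disparity peak precedes the diversity peak in at least 16/20,
and (iii) that the disparity peak falls within 5 Ma of the burst's end
in a majority. A replicate is valid only if the sampled MRCA predates
the epoch boundary by at least 2 Ma; otherwise no sampled lineage
witnesses the early epoch and the quantity being recovered does not
exist in that draw (invalid draws are redrawn deterministically).

What a green suite establishes: the pipeline's algebra is right (oracle
equivalence, distance/ordination identities, round trips), and under an
early-burst world the curves order events correctly. What it does not
establish: that a neutral Mk process can reproduce a genuine disparity
*decline*. Under neutral bounded-state evolution, between-lineage
variance saturates and then plateaus; real declines (as in the
motivating clade after the Oligocene) require the extinction of
disparate subclades or directional processes, neither of which the
default generator creates. Bear this in mind before reading biological
meaning into late-interval wiggles of simulated curves.

## 9. Numerical details and degenerate inputs

* Tip-age anchoring tolerance 1e-6 Ma; conflicting tip-age tables are
  hard errors naming the offending tips. Newick round trips preserve
  ages and rates to 1e-9 at the default 15 significant digits.
* Eigenvalues below `1e-8 x lambda_max` are dropped; an all-zero
  distance matrix is a hard "degenerate distances" error.
* Bins with < 2 members (disparity), < `n_sub` members (rarefaction) or
  0 branches (rates) are flagged undefined, never zero-filled;
  single-branch rate bins report SEM 0.
* A quirk worth knowing: the n−1 sample variance is *not* monotone
  under duplication — adding a second copy of an extreme lineage can
  raise a bin's sum of variances. Only a row at the bin centroid is
  guaranteed not to inflate it; the test suite asserts exactly that.
* All randomness (bootstraps, rarefaction, every simulator stage) is
  seeded explicitly; `run_pipeline()` derives each stage's seed from the
  single configuration seed and byte-identical reruns are asserted in
  the acceptance suite.
* NEXUS matrices may be interleaved, but every matrix line must begin
  with its (possibly quoted) taxon label; sequence continuation lines
  without labels are not supported.
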