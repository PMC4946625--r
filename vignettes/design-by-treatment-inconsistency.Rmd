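---
title: "Loop inconsistency models and the design-by-treatment interaction framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Loop inconsistency models and the design-by-treatment interaction framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netincon)
```

## The model

Network meta-analysis pools studies that each compare a subset of the
treatments of interest. A study's *design* is the set of treatments it
compares: an "AC design" study has arms A and C only. The *consistency
assumption* requires that indirect and direct evidence agree across the
network (the AB effect plus the BC effect equals the AC effect). It holds
automatically within a trial, but nothing forces it across designs.

`netincon` works with the contrast-level fixed-inconsistency model

$$\mu_{di}^{AJ} = \delta^{AJ} + \beta_{di}^{AJ} + \omega_d^{AJ},$$

where $\mu_{di}^{AJ}$ is the true effect of treatment $J$ versus the
reference $A$ in study $i$ of design $d$; $\delta^{AJ}$ are the $n-1$
*basic effects*; $\beta_{di}^{AJ}$ is a study-level heterogeneity term; and
$\omega_d^{AJ}$ is a design-level *inconsistency parameter*. Within-trial
consistency, $\mu_{di}^{IJ} = \mu_{di}^{AJ} - \mu_{di}^{AI}$, converts
reference-based parameters into the contrasts a study actually reports.
With a free $\omega$ for every design this is the *design-by-treatment
(DxT) interaction model*: every design estimates its own set of treatment
effects. Setting all $\omega = 0$ gives the consistency model.

## Inconsistency models as partitions

Every inconsistency model considered here is represented by a *consistency
partition*: a partition of the observed designs into groups assumed to
estimate the same treatment effects. A *loop inconsistency model* is the
partition induced by a treatment ordering — designs containing the first
treatment form one group; designs containing the second but not the first
the next; and so on:

```{r}
T4 <- enumerate_designs(c("A", "B", "C", "D"))  # all 11 possible designs
loop_model(c("C", "B", "D", "A"), T4)
```

The *union* of two models is the common refinement of their partitions
(all nonempty pairwise intersections of groups): the smallest
partition-form model that contains both.

```{r}
L1 <- loop_model(c("C", "B", "D", "A"), T4)
L2 <- loop_model(c("A", "B", "C", "D"), T4)
partition_union(L1, L2)
```

Two facts are verified machine-exhaustively by the package's test suite:

* **Separation**: any two distinct designs are placed in different groups
  by some loop model. The constructive witness puts a treatment belonging
  to exactly one of the two designs first, the rest alphabetical
  (`separation_witness()`, `verify_lemma()`).
* **Union of all loop models**: folding `partition_union()` over the loop
  models of all distinct orderings yields the discrete partition — every
  design its own group, i.e. the DxT model (`verify_theorem()`). Only
  $n!/2$ orderings need enumerating, because the order of the final two
  treatments does not affect the induced partition
  (`distinct_orderings()`).

Both are checked for $n = 3..6$ on the full design set and on random
observed subsets; the witness construction never needs unobserved designs,
so arbitrary observed networks are supported.

## From partitions to design matrices

`build_matrix()` turns a layout (one row per study contrast) and a
partition into a contrast-level design matrix: basic-effect columns
$\delta^{AJ}$ plus group-level inconsistency columns shared by all designs
in a group. Not all $\omega$ are identifiable; rather than hard-coding a
constraint scheme, the builder performs rank-revealing greedy elimination
in a deterministic canonical order (groups by smallest member design,
treatments lexicographic). Any valid constraint choice spans the same
column space, and the Wald statistic below is verified to be invariant to
the subset chosen. `inconsistency_df()` is the rank of the model matrix
minus the rank of the consistency matrix; `model_contains()` operationalizes
model containment as column-space inclusion.

### A limitation of the pairwise union at the matrix level

The union model *contains* the two loop models it is built from — at the
matrix level, the joined column spaces of the two loop-model matrices
always lie inside the union model's column space, and the cumulative union
over **all** orderings spans exactly the DxT column space (both are
tested). But the stronger statement that a *pairwise* union's column space
*equals* the join of the two loop-model column spaces is false in general:
at $n = 4$, 24 of the 66 distinct ordering pairs give a union model of
rank 10 while the concatenated matrices span rank 9 (e.g. orderings
A,B,C,D and C,B,A,D). This is the familiar gap between a two-way
interaction space and the sum of two main-effect spaces; the refinement
admits group-specific effects that no sum of the two coarser models can
produce. The test suite freezes one counterexample rather than asserting
the false equality.

## Estimation and the global test

`fit_gls()` fits any partition model by generalized least squares with
total covariance $V = \Sigma + \tau^2 R$, where $\Sigma$ is the known
within-study covariance and $R$ is the exchangeable heterogeneity
structure: variance $\tau^2$ per contrast, covariance $\tau^2/2$ between
contrasts of a multi-arm study. This is the conventional single-$\tau^2$
choice compatible with within-trial consistency; the model itself does not
fix one.

`estimate_tau2()` is a generalized DerSimonian–Laird moment estimator:
with $W = \Sigma^{-1}$ and $Q_0$ the residual statistic of the $\tau^2 = 0$
fit, it solves $E[Q_0] = (N - p) + \tau^2 c$ and truncates at zero. By
default heterogeneity is estimated residually under the DxT model, so that
inconsistency is not absorbed into $\tau^2$.

`wald_inconsistency_test()` fits the DxT model and computes
$Q = \hat\omega^\top \mathrm{cov}(\hat\omega)^{-1} \hat\omega$ over the
identifiable inconsistency estimates, referred to $\chi^2$ with the
inconsistency degrees of freedom. Because the DxT model contains every
loop inconsistency model, this single global test simultaneously tests the
null of no inconsistency in all of them — no multiplicity adjustment is
needed or applied. A single-design network yields a flagged degenerate
result ($Q = 0$, df $= 0$, $p$ undefined).

## The synthetic-data generator

`simulate_network()` realizes the model above as a generative process, at
the contrast level: per study of design $d$ with baseline $b$, true
contrasts $(\delta_J + \omega_{d,J}) - (\delta_b + \omega_{d,b})$ plus a
heterogeneity draw ($\tau^2$ exchangeable) plus sampling noise with a
shared-baseline-arm covariance (per-arm variance `var_scale`, so contrast
variance `2 * var_scale` and within-study covariance `var_scale`), which is
recorded as the known within-study covariance. Per-study random substreams
are derived deterministically from the master seed, so partial reruns
reproduce.

Defaults were fixed once as the package's stated world and are not tuned
to test outcomes: `var_scale = 0.05` (contrast variance 0.1, a realistic
magnitude for log odds ratios from moderate trials), triangle basic
effects (0.2, 0.5), four-treatment effects (0.2, 0.5, 0.8), inconsistency
offsets placed on the loop-closing BC design (treatment C), two studies
per design for the triangle and star scenarios, and one study per design
for the full-T scenario, mirroring the one-study-per-design T network used
in the combinatorial analysis.

What the generator emulates: multi-study networks, correlated contrasts
from multi-arm trials, between-study heterogeneity, and design-level
inconsistency offsets. What it does not: arm-level (e.g. binomial)
likelihoods and the sampling error of estimated within-study variances,
missing arms, or outcome-specific scales. A green simulation test
therefore establishes calibration under normal contrasts with *known*
within-study covariance — the setting in which the Wald statistic is
exactly $\chi^2$ — not performance under variance estimation error.

## Numerical choices and edge cases

* Ranks use `qr()` with tolerance `1e-8`; all matrix entries are in
  {-1, 0, 1}, so ranks are numerically unambiguous.
* Canonical forms everywhere: designs print as sorted label strings,
  groups sort by smallest member, partitions compare by identity of
  canonical forms; radix sorting pins the C locale.
* Exhaustive ordering enumeration refuses $n > 8$ (8!/2 = 20160 models)
  unless forced; the constructive witness covers any $n$.
* Degenerate inputs: single-design networks give df 0 and a flagged
  degenerate test; saturated models refuse to estimate $\tau^2$ and ask
  the caller to supply one (the test then warns and uses 0 if asked for
  `"auto"`).
* Disconnected networks are not special-cased: ranks are computed as-is.
  Basic effects linking disconnected components are then not estimable and
  `fit_gls()` reports the singular normal equations by name.

## Known limitations

Random-effects treatment of the inconsistency parameters, Bayesian
estimation, arm-level likelihoods, node-splitting/local tests, and network
visualization are out of scope. The inconsistency parameters are fixed
effects throughout.
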