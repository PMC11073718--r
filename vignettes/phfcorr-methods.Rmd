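---
title: "Correlation-based decision making with probabilistic hesitant fuzzy sets"
author: "phfcorr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-based decision making with probabilistic hesitant fuzzy sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phfcorr)
```

## The model

When several experts evaluate the same object, their judgements are rarely a
single number. A *hesitant fuzzy element* (HFE) records the set of membership
degrees in $[0,1]$ the group hesitates between; a *probabilistic hesitant
fuzzy element* (PHFE) additionally attaches a probability to each degree,
recording how much of the group supports each value:

$$h(p) = \{\gamma_1|p_1,\ \gamma_2|p_2,\ \dots,\ \gamma_l|p_l\},
\qquad 0 \le \gamma_i \le 1,\quad \textstyle\sum_i p_i = 1 .$$

A *probabilistic hesitant fuzzy set* (PHFS) assigns one PHFE to each item of
a finite universe — in decision problems, one evaluation per criterion. Two
scalar summaries drive all comparisons:

* the **score** $s(h) = \sum_i \gamma_i p_i$ (probability-weighted mean
  membership; larger is better), and
* the **deviation** $\delta(h) = \sum_i (\gamma_i - s(h))^2 p_i$
  (dispersion about the score; at equal score, smaller is better — less
  hesitation).

`phfe()`, `phf_score()`, `phf_deviation()` and `phf_compare()` implement
this layer, with validation that signals distinct condition classes for
out-of-range memberships, out-of-range probabilities, and probability sums
away from 1 (tolerance `1e-9`; inputs are never silently renormalized).

## Information-energy correlation

The package's central quantity treats the per-entry products
$F_j = \gamma_j p_j$ as the coordinates of an element. The *information
energy* of a PHFS is

$$\psi(A) = \sum_{i=1}^{n} \frac{1}{l_i} \sum_{j=1}^{l_i}
  \bigl(\gamma_{ij}\, p_{ij}\bigr)^2 ,$$

a self-inner-product, and the cross term between two PHFSs over the same
universe is

$$C_1(A,B) = \sum_{i=1}^{n} \frac{1}{l_i} \sum_{j=1}^{l_i}
  \gamma^A_{ij} p^A_{ij}\, \gamma^B_{ij} p^B_{ij} .$$

Four normalizations give the correlation coefficients:

$$\rho_1 = \frac{C_1(A,B)}{\sqrt{\psi(A)\,\psi(B)}}, \qquad
  \rho_2 = \frac{C_1(A,B)}{\max\{\psi(A), \psi(B)\}},$$

and their weighted analogues $\rho_3,\rho_4$ in which every per-item term —
the cross term and both energies — is multiplied by an item weight $w_i \ge 0$,
$\sum w_i = 1$. By the Cauchy–Schwarz inequality all four lie in $[0,1]$,
equal $1$ at $A = B$, are symmetric, and satisfy $\rho_2 \le \rho_1$,
$\rho_4 \le \rho_3$ (the maximum dominates the geometric mean). With uniform
weights $\rho_3$ and $\rho_4$ reduce exactly to $\rho_1$ and $\rho_2$. The
test suite checks each of these properties on $10^4$ seeded random pairs.

### Alignment conventions

Comparing elements of different lengths requires a convention; the package
fixes three rules, chosen so that every reproducible worked table in the
underlying method is recovered exactly:

1. **Canonical order.** Entries are sorted ascending by $F = \gamma p$
   (ties broken by membership then probability, ascending, stable). Because
   only the products $F_j$ enter the coefficients, the tie-break affects
   reproducibility of intermediate displays but can never change a
   coefficient value.
2. **Pessimistic padding.** The shorter element is extended *in front* with
   copies of the minimum-$F$ entry's membership at probability $0$ (so
   $F = 0$: the padding is inert in every sum and preserves the probability
   total and the score). Note the padded membership is the minimum-$F$
   entry's membership, which is not always the smallest membership value —
   with $\{0.2|0.7,\ 0.3|0.3\}$ the padding value is $0.3$ ($F=0.09$), not
   $0.2$ ($F=0.14$). An optimistic variant (append the maximum-$F$
   membership at probability 0) is available behind the `padding` flag;
   pessimistic is the default everywhere.
3. **Length convention.** The cross term divides by the *aligned* length
   $l_i = \max(l^A_i, l^B_i)$, while the energies in every denominator use
   each set's *own unpadded* lengths. This asymmetry is deliberate: it is
   the only combination that reproduces the published worked arithmetic,
   and with it $\rho_k(A,A) = 1$ holds exactly since no padding occurs at
   $A = B$.

Zero information energy (all memberships or all probabilities zero) makes
the coefficients undefined; the functions signal `phf_zero_energy_error`
rather than letting `NaN` propagate into a ranking.

### Baselines, and why the energy form is needed

Two older correlation families ship for comparison:

* `song_rho()` — a Pearson-style coefficient of the two per-element *mean*
  vectors ($m_i = \sum_j \gamma_j p_j$), with a weighted form. Its known
  flaw: any two PHFSs whose element means coincide correlate at exactly 1,
  however different their hesitation structure. The built-in `"three-set"`
  fixture demonstrates this — all three pairwise baseline coefficients are
  1 while $\rho_1$ separates the sets (0.9302, 0.7646, 0.7850).
* `hfs_rho()` — the probability-free hesitant-fuzzy coefficient (values
  sorted ascending, shorter element padded by repeating its minimum value,
  same own-length denominator convention). It quantifies what is lost when
  preference probabilities are discarded. The weighted variant sits behind
  the `w` argument; the unweighted form is the default because that is the
  form under which the published comparison figures reproduce.

The mixed mean/variance/length-rate coefficient from the same literature is
out of scope: its component formulas are defined only in an external
reference.

## The group decision pipeline

`phf_evaluate()` runs the ten-step elicitation-to-ranking procedure:

1. Each of $k$ experts rates every alternative under every criterion on a
   nine-term linguistic scale (VL, VLL, L, ML, M, MH, H, HVH, VH), mapped
   to Saaty's 1–9 integers.
2. Criteria weights: experts also rate each criterion's importance; the
   Saaty values are combined with the expert weights into an integrated
   weight per criterion and normalized to sum to 1
   (`criteria_weights()`). Explicit weights may be supplied instead.
3. Each expert's matrix is multiplied by the expert's weight
   (`weighted_numeric_matrices()`); the $k$ values of each
   alternative-criterion cell are collected, sorted ascending, into a
   hesitant fuzzy group matrix (`group_matrix()`).
4. Normalization (`normalize_group_matrix()`): benefit columns are divided
   by the global column maximum; for cost columns the global column minimum
   is divided by each value. Every column's best raw value maps to exactly
   1 and all outputs lie in $(0,1]$.
5. Equal values within a cell merge with probability multiplicity$/k$
   (`to_phf_matrix()`), giving the PHF group decision matrix.
6. The *ideal alternative* takes, per criterion, the cell with maximal
   score, ties broken by minimal deviation, then by lowest alternative
   index (`ideal_alternative()`).
7. Every alternative's row is correlated with the ideal via $\rho_3$ and
   alternatives are ranked by descending coefficient
   (`rank_alternatives()`). Exact coefficient ties keep their input order
   and are annotated rather than broken.

Problems that already arrive as a PHF decision matrix (the rank-reversal
and comparison fixtures do) enter the pipeline at step 6.

### Rounding modes

Published worked tables in this field round the normalized matrix to two
decimals before building the PHF matrix, and those rounded values are the
only way to recover the published coefficients digit for digit. The
pipeline therefore has two modes:

* `rounding = "precise"` (default) — full double precision throughout;
  value merging in step 5 uses a `1e-9` tolerance.
* `rounding = "paper"` — normalized entries rounded **half-up** to 2
  decimals (half-up, not banker's rounding: $0.625 \to 0.63$, exactly as
  the reference tables do), then exact-equality merging.

In the bundled case study both modes produce the same final ordering; only
the coefficient digits differ. The built-in case-study fixture also pins
the published two-decimal criteria weights $(0.21, 0.31, 0.39, 0.09)$;
`criteria_weights()` itself returns the exact normalization
$(0.2118, 0.3176, 0.3765, 0.0941)$ of the integrated weights
$(4.5, 6.75, 8, 2)$ — the published 2-dp vector is not the rounding of the
exact one (its third entry would round to 0.38), so the two are kept as
distinct, documented artifacts rather than silently reconciled.

## The random generator

`random_phfs(n, max_len, scheme, seed)` draws property-test inputs: element
lengths uniform on $1..max\_len$, memberships uniform on $[0,1]$, and
probabilities either uniform draws normalized to sum 1
(`"uniform-dirichlet"`) or exactly equal (`"equal"`). This emulates the
*structure* of expert hesitation (ragged lengths, arbitrary preference
splits) but none of the features of real elicitation: real matrices have
probabilities on a $1/k$ grid, strongly correlated criteria, and rounded
membership values. Passing property tests on these inputs therefore
establishes the algebraic identities (symmetry, range, dominance,
degeneration, Cauchy–Schwarz) — not calibration on real evaluations. A
fixed seed gives byte-identical output; the generator restores the global
RNG state when a seed is supplied.

## Numerical choices

* Probability-sum tolerance `1e-9`; validation never renormalizes.
* Coefficient reference values are compared at absolute tolerance `5e-5`
  (published values carry four decimals).
* Half-up rounding is implemented as
  $\lfloor 100x + 0.5 + 10^{-9}\rfloor / 100$; the guard absorbs binary
  representation error just below a half.
* The cross term multiplies the two per-entry $F$ products,
  $(\gamma^A p^A)(\gamma^B p^B)$, rather than chaining four factors, so
  that $\rho(A,B)$ and $\rho(B,A)$ are bit-identical.
* Test problem sizes: universes of 2–5 items, elements of 1–6 entries,
  $10^4$ random pairs for the property suite and 50–500 for per-operation
  checks — ample for identities that hold exactly, while keeping the full
  suite fast.

## Known limitations

* The ideal-alternative rule is the stated max-score/min-deviation
  selection. Two published comparison tables select a different cell than
  this rule implies; the corresponding fixtures pin those published ideal
  rows as *inputs* so the downstream coefficients can still be reproduced,
  and the discrepancy is documented in the fixture notes.
* One published comparison coefficient (the fourth alternative of the
  mean-correlation comparison) does not recompute under any convention the
  package implements; the fixture marks only the first three alternatives
  as reproducible reference values.
* PHFEs cannot express neutrality or opposition — only graded membership
  with preference probabilities. Extensions (interval-valued, dual,
  picture, linguistic-term) are out of scope.
* Expert weights default to $1/k$; arbitrary normalized weights are
  accepted, but the elicitation scheme assumes every expert rates every
  cell — there is no missing-data handling.
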