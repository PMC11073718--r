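# phfcorr

Correlation coefficients and group decision making for **probabilistic
hesitant fuzzy sets** (PHFSs).

When a panel of experts evaluates alternatives — for example, which orphan
drug for a rare disease should enter a reimbursement list — each judgement
is rarely one number. A probabilistic hesitant fuzzy element (PHFE) records
the membership degrees the panel hesitates between together with the share
of the panel behind each value, written `{γ₁|p₁, …, γₗ|pₗ}` with
`γᵢ ∈ [0,1]` and `Σpᵢ = 1`. A PHFS assigns one PHFE per criterion. This
package is for health-decision and multi-criteria-decision analysts who
need to (a) measure how similar two such evaluation profiles are and
(b) rank alternatives against an ideal profile.

## The statistic at its core

The information-energy correlation treats the per-entry products
`F = γ·p` as coordinates. With

&nbsp;&nbsp;ψ(A) = Σᵢ (1/lᵢ) Σⱼ (γᵢⱼ pᵢⱼ)²  (information energy)

&nbsp;&nbsp;C₁(A,B) = Σᵢ (1/lᵢ) Σⱼ γᵢⱼᴬ pᵢⱼᴬ γᵢⱼᴮ pᵢⱼᴮ  (cross term)

the coefficients are

&nbsp;&nbsp;ρ₁ = C₁(A,B) / √(ψ(A)·ψ(B)),&nbsp;&nbsp;
ρ₂ = C₁(A,B) / max{ψ(A), ψ(B)},

plus weighted forms ρ₃, ρ₄ in which each universe item's terms carry a
weight `wᵢ`. All four lie in [0,1], equal 1 at A = B, and satisfy
ρ₂ ≤ ρ₁, ρ₄ ≤ ρ₃. Elements are aligned before comparison: entries sorted
ascending by `F`, the shorter element padded in front with its minimum-`F`
membership at probability 0 (pessimistic criterion); the cross term uses
the aligned length per item while the denominators keep each set's own
lengths. Two baselines ship for contrast: the mean/variance (Pearson-style)
PHFS coefficient, which degenerates to 1 whenever element means coincide,
and the probability-free hesitant-fuzzy coefficient.

On top of the coefficients sits a ten-step multi-criteria group decision
pipeline: linguistic ratings (VL … VH, Saaty 1–9 scale) → criteria weights
→ expert-weighted numeric matrices → hesitant fuzzy group matrix →
benefit/cost normalization → PHF group matrix → ideal alternative
(max score, ties by min deviation) → ranking by weighted correlation ρ₃
with the ideal.

## A worked example

Two panels give the evaluations `{0.2|0.6, 0.8|0.4}` and
`{0.6|0.2, 0.4|0.8}`:

```r
library(phfcorr)
h1 <- phfe(c(0.2, 0.8), c(0.6, 0.4))
h2 <- phfe(c(0.6, 0.4), c(0.2, 0.8))
phf_score(h1); phf_score(h2)       # 0.44  0.44  — tied on score
phf_deviation(h1); phf_deviation(h2)  # 0.0864  0.0064
phf_compare(h1, h2)                # -1: h1 < h2 (more hesitation at equal score)
```

Correlating two three-item PHFSs (one element needs padding):

```r
fx <- phf_fixture("energy-pair")
phf_correlation(fx$A, fx$B, method = "rho1")
#> PHFS correlation (rho1): 0.6764
#>   energy A: 0.0694  energy B: 0.1751  cross: 0.0746
```

The bundled orphan-drug case study — five narcolepsy treatments, four
equally weighted medical experts, criteria safety / effectiveness (cost) /
economy / social value — runs end to end from the linguistic tables:

```r
cs <- phf_fixture("case-study")
ev <- phf_evaluate(cs$problem, rounding = "paper")
ev
#> PHF group decision evaluation (paper mode)
#> Criteria weights: 0.21, 0.31, 0.39, 0.09
#> Correlation with the ideal alternative (rho3):
#>   1. A3     0.9589
#>   2. A2     0.8932
#>   3. A1     0.7708
#>   4. A4     0.6794
#>   5. A5     0.4699
#> Ordering: A3 > A2 > A1 > A4 > A5
```

A3 correlates most strongly with the ideal alternative, so it is the drug
the method selects; the coefficients are each alternative's weighted
information-energy correlation with the per-criterion best evaluations.
Every intermediate artifact (`ev$group`, `ev$normalized`, `ev$phf`,
`ev$ideal`) is returned for audit. `rounding = "paper"` reproduces
published two-decimal tables; the default `"precise"` mode keeps full
precision (same ordering here).

A command-line interface wraps the same functions
(`inst/cli/phf.R`): `score`, `corr`, `evaluate` (with a JSON audit
report), and `fixtures list|run`.

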