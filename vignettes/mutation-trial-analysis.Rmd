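---
title: "Models and methods behind mutbreedr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mutbreedr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutbreedr)
```

`mutbreedr` packages the statistical workflow of a multi-generation
mutagenesis field trial in a self-pollinated grain legume: two cowpea
varieties, a control plus gamma-ray (100--1,000 Gy), sodium-azide
(0.01--0.1 %) and combined dose series, 300 seeds per treatment, and ten
quantitative traits scored over the M2 and M3 generations with 30
replications. This vignette documents the models, the tunable
parameters, the numerical conventions, and the design decisions that
were genuinely open.

## The data model

Everything travels as a long-format trait table: one row per (variety,
generation, treatment, line, replicate, trait). A *line* is a putative
mutant family within a treatment; a *replicate* is a plot observation of
that line. The simulator generates

\[
y_{\ell k t} = \mu_t + \delta_{jt} + g_{\ell t} + e_{\ell k t},
\qquad g_{\ell t} \sim N(0, \sigma^2_{g,t}),\quad
e_{\ell k t} \sim N(0, \sigma^2_{e,t}),
\]

for line \(\ell\), replicate \(k\), trait \(t\) and treatment \(j\).
Line effects are drawn once per line and persist across generations --
that is what makes heritability operationally meaningful across
selection cycles -- while plot errors are redrawn every generation.
Normality is assumed throughout, which is also the implicit assumption
of the trial's one-way ANOVA.

The yield trait is not parameterized directly. With path coefficients
\(b\) on a standardized scale, yield at each plot is

\[
\mathrm{PY} = \mu_{PY} + \delta_{j,PY} +
  s_{PY}\Big(\textstyle\sum_t b_t z_t + \varepsilon\Big),
\qquad z_t = \frac{y_t - \mu_t - \delta_{jt}}{\sqrt{\sigma^2_{g,t}+\sigma^2_{e,t}}},
\]

with \(s_{PY} = \sqrt{\sigma^2_{g,PY}+\sigma^2_{e,PY}}\) and
\(\varepsilon \sim N(0, \sigma^2_{res})\),
\(\sigma_{res} = \sqrt{1-\sum b_t^2}\) by default so the standardized
yield has unit variance when components are uncorrelated. Two
consequences are worth knowing. First, path analysis on plot-level data
recovers \(b\) consistently (the test suite checks ±0.05 at 1,000
lines); on line means it would not, because averaging replicates inflates
the heritable share of the components asymmetrically. Second, yield
heritability is *induced*: with component heritability 0.8 and the
default \(b\), plot-level yield h² comes out near 0.5 rather than the
0.8--0.96 the trial reports for yield. The simulator is a device for
validating estimators, not a generative fit to the published tables.

## Simulator defaults and what they emulate

`cowpea_sim_params()` calibrates the generator to the published trial:
grand means are the printed control means, treatment shifts the printed
treated-minus-control differences, and per-trait genotypic variance is
back-computed from the median printed GCV of the treated populations,
\(\sigma^2_g = (\mathrm{GCV}/100 \cdot \bar x)^2\), with plot error set
for a nominal plot-basis heritability of 0.8. Default path coefficients
put the largest direct effects on seed weight (0.6) and seeds per pod
(0.4), a moderate one on pods per plant (0.2), small ones on harvest
index (0.15) and branches (0.05), and a small negative one on pod
length (−0.1) -- the qualitative ordering the trial reports.

Germination declines logistically on a composite dose axis:
\(p(d) = g_0\,\sigma(-s(d-d_{50}))/\sigma(s\,d_{50})\) with baseline
\(g_0 = 0.9\), slope \(s = 0.03\) per Gy-equivalent and
\(d_{50} = 450\) Gy-equivalents, so germination halves relative to the
control midway between the fourth and fifth dose levels. An SA
concentration of 0.01 % is equated to 100 Gy-equivalents. For combined
treatments the composite is **saturating**, not additive:
\(d = \max(\gamma, w\,\mathrm{SA}) + v\,\min(\gamma, w\,\mathrm{SA})\)
with \(v = 0.1\). The reported screen retains G1--G4, S1--S4 and
G1+S1--G4+S4 while dropping every fifth-level dose; a strictly additive
composite cannot order the series that way (G4+S4 would always exceed
G5 on the dose axis), whereas the saturating form places G4+S4 at 440
Gy-equivalents -- the most severe retained treatment -- and G5/S5/G5+S5
at 500+. This is a deliberate design choice: the trial defines no joint
dose metric, and sub-additivity of joint mutagen injury at germination
is the only reading consistent with its retained set.

The exclusion rule itself is boundary-inclusive: a treatment is retained
when its germination percentage is **at least** half the control's,
because the screen drops doses causing *more than* a 50 % reduction.

What the generator does **not** emulate: field spatial structure and
block effects (plots are exchangeable), genotype-by-environment
interaction, non-normal trait distributions, segregation within lines,
linkage between traits beyond the yield path, and any sequence-level
mutation process. Passing tests therefore demonstrate that the
estimators recover the parameters of *this* model, not that real field
data satisfy it.

## Generations, selection, and the control

`simulate_generations()` advances each generation by truncation
selection: within each treated population, lines are ranked by their
replicate-mean of the selection trait (yield by default, top 30 as in
the trial's advancement of "30 high yielding" lines) and the selected
subset carries its line effects forward; plot errors are redrawn. If the
rule names specific treatments (the default pipeline advances G1, G2,
S1, S2, G1+S1, G2+S2, the six populations the trial carried into M3),
the rest are dropped. The control is advanced by a *seeded random*
subsample of the same size: the trial applies no selection to its
check, and random subsampling keeps the design balanced so the Duncan
test's equal-n requirement holds in later generations. Realized gain
deltas between generations then reflect selection response in the
treated populations against an unselected control.

The trial never states whether its "n = 30" means 30 replicate plots or
30 plants; the simulator exposes `lines_per_treatment` and
`replications` separately so either reading is representable. The
default design uses 100 lines in the first generation (room for 30 %
selection intensity) with 30 replications.

## Estimation conventions

- **Variance components.** \(\hat\sigma^2_g = (MSG - MSE)/r\) from the
  balanced one-way ANOVA among lines. A negative estimate is truncated
  to zero with a classed warning (`mutbreedr_negative_sigma_g`) -- the
  conventional resolution; it is a warning, not an error, because
  negative moment estimates arise routinely under low heritability.
- **Phenotypic variance** is defined on the plot basis,
  \(\sigma^2_p = \sigma^2_g + MSE\). The trial never defines
  \(\sigma^2_p\); this choice is the one under which the printed tables
  satisfy the GA identity \(GA = k\cdot GCV\cdot\sqrt{h^2/100}\) (the
  package asserts that identity on its own output to 1e-9 relative
  tolerance).
- **GCV** uses \(\sqrt{\sigma^2_g}\). The trial's typeset formula lost
  the radical, but its printed values are consistent only with the
  square-root (standard Allard) form.
- **k = 2.64** (1 % selection intensity) is the default and is
  configurable everywhere it appears.
- **Rounding** happens only at presentation: report renderers round half
  away from zero to 2 decimals, matching the printed style
  `93.75^h ± 0.32`; all internal arithmetic is full precision.
- A handful of printed GA cells (e.g. plant height, pod length) violate
  the GA identity that the rest of the tables satisfy; these are treated
  as typesetting errors and are not reproduced or asserted.

## Duncan's multiple range test

Critical values come from the studentized range distribution at the
protected level \(\alpha_p = 1-(1-\alpha)^{p-1}\) via `stats::qtukey`,
not from the historical 1955 tables, so any error degrees of freedom are
supported; the test suite checks them against an independent
numerical integration of the studentized-range CDF to 1e-4. The
stepwise rule is: visit spans of the descending means widest first; a
span is homogeneous if it lies inside an already-accepted span or its
range is at most LSR(width). Letters are assigned per maximal
homogeneous span, so two groups share a letter exactly when the
procedure fails to separate them, and the largest mean always carries
"a". Ties in means break lexicographically by group label, making
output deterministic. With MSE = 0 the LSR degenerates to 0: distinct
means all get distinct letters, identical means share "a". Only the
balanced (equal n) test is implemented; the harmonic-mean variant for
unequal n is out of scope and unequal group sizes are an error.

Note an inferential subtlety validated in the suite: the error term for
comparing treatment means is the plot-level MSE of the one-way ANOVA
across treatments, as in the trial's methodology. Under a null with
genuine line effects inside treatments, plot-level MSE understates the
variance of a treatment mean and the letters separate more often than
the nominal rate; the type-I calibration test therefore uses an iid
null. Users comparing treatments in data with strong family structure
should interpret letters accordingly.

## Correlations and path analysis

Spearman rank correlation (average ranks on ties) is the default for
descriptive trait association, with p-values from the t approximation on
n−2 degrees of freedom and stars at 0.05/0.01/0.001. A constant trait
has no defined rank correlation: its cells are NA and the trait is
listed as degenerate, never silently zeroed.

Path analysis defaults to **Pearson** input even though the descriptive
matrices are Spearman: the decomposition identities
(\(r_{iy} = b_i + \sum_{j\ne i} r_{ij} b_j\), \(E_1^2 = 1-\sum b_i r_{iy}\))
hold only for the same matrix that generated the yield correlations.
The predictor set defaults to the six yield components the trial used
(PPP, BPP, SPP, SW, PL, HI); plant height and phenology were excluded
there for negligible effects. Systems with reciprocal condition number
below 1e-10 are rejected with advice to drop a collinear trait. A
negative residual variance (explained share numerically above 1) clips
E1 to zero and sets a flag. The trial's own printed direct effects
(values like 6.18) exceed 1 and evidently come from an unstandardized
covariance-structure fit whose scaling is unrecoverable without raw
data; the package's conformance is to the algebraic identities and to
recovery of known coefficients under the generator.

## Multivariate profiling

Euclidean distances are computed on **raw** trait means by default: that
choice reproduces the trial's printed minimum inter-population distance
to within rounding (2.6715 vs the printed 2.66, pair G1+S1/S3 of the
M2 Gomati VU-89 table), while standardized distances do not.
Standardization remains a flag. The printed *maximum* distance (29.00)
is not reproducible from the printed means (which give 29.82); the
trial's exact input matrix is ambiguous and the discrepancy is
documented rather than forced.

UPGMA clustering is delegated to `stats::hclust(method = "average")`
behind the `upgma()` surface; labels are sorted first so output is
independent of row order, and tie handling is hclust's deterministic
rule rather than an explicit smallest-label convention. Flat clusters
are extracted by count k (the trial reports 5 and 7 clusters), profiles
are member means, and inter-cluster distances are average member-pair
distances, consistent with the linkage criterion. Dendrograms export to
Newick via `ape`.

PCA is an eigendecomposition of the correlation matrix (mixed trait
units make covariance PCA meaningless here), with scores from the
centred, scaled data. cos2 is the squared variable-component
correlation, so each variable's cos2 sums to 1 across components and
per-component contributions sum to 100 %. Eigenvector signs follow a
deterministic convention -- the largest-|loading| variable loads
positively -- so results are platform-reproducible. The trial's printed
variance fractions (62.4 %/17.6 %) came from its unavailable raw data;
on the printed mean matrix the package computes its own fractions and
asserts only the spectral identities.

## Genetic gain

Gain is operationalized as the percent yield advantage over the
same-generation control,
\(100\,(\bar y_{j} - \bar y_{C})/\bar y_{C}\) -- the only definition
under which all four gain figures the trial reports (28.75 %, 45.73 %,
and the M2-to-M3 increases 9.28 % and 14.15 %) follow exactly from its
printed plant-yield means; the "increase in genetic gain" between
generations is the difference of these percentages. The breeder's
equation (expected gain) is deliberately out of scope: only realized,
mean-based accounting is reported.

## Pigment quantification

Chlorophyll and carotenoids follow the Arnon-style equations with the
parenthesization fixed to the dimensionally consistent forms:
\(\mathrm{chl} = (20.2\,OD_{645} + 8.02\,OD_{663})\,V/(1000\,W)\) and
\(\mathrm{car} = (7.6\,OD_{480} - 1.49\,OD_{510})\,V/(d\cdot 1000\,W)\)
in mg per g fresh mass, with V the extract volume (mL), W the tissue
mass (g) and d the light path (1.4 cm default). The printed typography
is garbled; these are the standard source forms. Chlorophyll, as
printed, does not divide by d -- implemented exactly so, and flagged
here. A negative carotenoid bracket is physically impossible and is
clipped to zero with a classed warning. Assay-based quantities (nitrate
reductase, protein, Fe/Cu/Zn) have no printed equations and are treated
as data columns only.

## Numerical conventions and degenerate inputs

- All randomness flows through one integer seed per entry point; global
  RNG state is saved and restored, and identical inputs give
  byte-identical outputs.
- ANOVA mean squares below 1e-12 of the squared data scale are zapped to
  exactly zero so constant cells report MSG = MSE = 0 with an undefined
  (NA) F rather than numerical dust.
- Unbalanced cells, missing treatment/trait cells, non-numeric or
  duplicated CSV records, singular path systems, and zero-variance
  traits under standardization are all hard errors naming the offender;
  negative variance estimates and negative carotenoid brackets are
  warnings with defined results.
- Test problem sizes are chosen to make the statistical assertions
  sharp at small cost: variance-component recovery uses 200 cells of 30
  lines x 30 replicates; path recovery uses 100 seeds at 1,000 lines x 2
  replicates; the variance-conservation check uses 2,000 lines x 5
  replicates so the dominant sampling term (the line-effect sample
  variance) sits well inside the 5 % band; Duncan conformance uses 500
  random instances of up to 5 groups against an exhaustive-span oracle.

## Known limitations

- The simulator's independence assumptions (no trait correlations
  beyond the yield path, no spatial or block structure) make it a clean
  estimator testbed but an idealized field.
- Yield heritability is induced by the path structure and sits below
  the published yield h² range; analyses that need a specific yield h²
  should parameterize yield directly (set `path_coefficients = NULL`).
- Only the balanced DMRT is provided; unbalanced layouts error rather
  than silently switching to a harmonic-mean approximation.
- Published letter strings, PCA fractions, cluster memberships, and
  AMOS-scaled direct effects depend on raw field data that was never
  deposited; the package validates those components against algebraic
  identities, brute-force oracles, and generator ground truth instead.
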