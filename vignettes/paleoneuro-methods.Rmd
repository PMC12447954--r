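---
title: "Models and methods: quantitative paleoneurology from endocast tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: quantitative paleoneurology from endocast tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoneuro)
```

## The problem

Mammalian brain evolution over the Cenozoic is studied through cranial
endocasts: casts (natural, physical, or digital) of the endocranial
cavity, whose size and surface relief track the brain closely in
mammals. From a measurement table — one row per endocast or brain, with
surface areas, neocortex area, length, volume, body mass, and geologic
age in the cgs convention (cm², ml, g; ages in Ma with negative values
in the past) — this package computes the classical, deliberately
phylogeny-naive statistics of comparative paleoneurology. These methods
predate modern phylogenetic comparative methods and are retained here on
purpose: the package reproduces a historical analysis style so its
outputs can be compared against the literature that used it. Nothing
here corrects for shared ancestry, and none of the outputs should be
read as if it did.

## Brain–body allometry and the encephalization quotient

Across species, brain size follows body mass as a power law,
\(E = b\,P^{\alpha}\), linear on log-log axes:
\[\log_{10} E = \alpha \log_{10} P + \log_{10} b.\]

`loglog_fit()` (and its wrapper `fit_brain_body()`) estimates
\(\alpha\) and \(\log_{10} b\) by ordinary least squares of
\(\log_{10} E\) on \(\log_{10} P\). OLS — not reduced major axis — is
the default because the historical analyses used bivariate regression of
brain on body; an RMA slope (`method = "rma"`, equal to the OLS slope
divided by \(|r|\)) is available for users who prefer a symmetric
estimator, but it is never the default. All logarithms are base 10: the
slope is base-invariant and the intercept is conventionally reported in
log10 units.

The encephalization quotient takes the exponent as a *theoretical*
constant instead of an estimate:
\[EQ = \frac{E}{b\,P^{2/3}}, \qquad b = 0.12,\ \alpha = \tfrac{2}{3}
\text{ (the exact fraction)}.\]
The 2/3 reflects surface-to-volume scaling of the body; 0.12 is the
classical mammalian intercept. The packaged table never states its
intercept explicitly, so `derive_b()` recovers it by back-solving
\(b = E/(EQ\,P^{2/3})\) on every row with a printed quotient and taking
the median; the result (0.1199) pins 0.12 as the generating constant.
`eq_quotient()` is tagged cgs-only (`units = "cgs"`): with `E` in
liters or `P` in kilograms the quotient is meaningless, so other unit
systems are rejected rather than silently accepted.

`body_mass_from_length()` exposes the companion relation
\(P = 0.021\,L^{3.03}\) (body mass from body length, cgs). The table's
length column is *endocast* length, a different quantity, so the package
never uses this relation to impute missing body masses; it is provided
for completeness only.

## Neocorticalization

The neocortex is delimited on an endocast by the rhinal fissure; its
surface share is
\[\%NC = 100 \cdot \frac{NC}{S - OB},\]
with olfactory bulbs excluded from the denominator because bulbs are
frequently broken or missing on natural casts. `pct_neocortex()`
enforces \(0 < NC \le S-OB\); a violation signals mis-paired
measurements rather than a computable ratio.

Wherever both areas are present the package *recomputes* the percentage
instead of trusting the printed column. This matters: the transcribed
table contains one grossly inconsistent printed cell (*Equus
occidentalis*, printed 85.19 vs recomputed 58.66) which `validate_specimens()`
flags and all downstream fits automatically bypass. The printed value is
used only as a fallback when an area is missing.

`nc_trend()` fits OLS of %NC on age in Ma. Its population defaults to
every row with both quantities (cetaceans drop out automatically — no
rhinal fissure, no %NC); two flags narrow it: `exclude_failed` removes
rows whose printed percentage fails validation, and `exclude_recent_Ma`
removes very young fossil material (e.g. tar-pit specimens well under
1 Ma), which is dated almost at zero yet measured like extant animals
and can therefore pile up at the modern end of the regression. On the
packaged table the default fit uses 152 rows and yields about +0.75
percentage points per Ma (≈7.5 per 10 Ma), climbing from ≈14% at −60 Ma
to ≈59% at present — the tests assert ranges, not point values, because
the published summaries of this trend are themselves round figures
(15→58% in one place, 20→50% in another, ≈5%/10 Ma in a third) that
imply slightly different slopes.

`nc_eq_profile()` bins specimens by EQ (equal-width bins, default width
0.5) and averages %NC per bin. The "plateau" of neocortical expansion is
not numerically defined in the classical literature; here it is
operationalized as the smallest bin edge beyond which successive
occupied-bin means change by less than 2 percentage points (tunable).
With the default width the sparse high-EQ bins of the packaged table are
single specimens whose means fluctuate by ~3 points, so no plateau is
detected there and the profile honestly reports `NA`; the specimen
maximum (80.76%, a chimpanzee braincast) is reported alongside.

## Convex polygons in brain–body space

`convex_polygon()` builds the minimum convex polygon of a point set in
\((\log_{10} P, \log_{10} E)\) space, the classical device for
delimiting class-level encephalization grades. Conventions are chosen to
make results canonical and tests deterministic: vertices are ordered
counter-clockwise starting from the lexicographically smallest vertex;
vertices collinear with their neighbours are removed (strict convexity);
duplicated input points never change the hull. Fewer than three distinct
points, or a fully collinear set, is a degeneracy error, not an empty
polygon.

`classify_point()` places a specimen relative to a polygon: `inside` /
`on_boundary` by standard convex containment; otherwise `above` or
`below` by comparing \(\log_{10} E\) with the upper or lower boundary
chain evaluated at the specimen's \(\log_{10} P\) — defined only within
the polygon's horizontal extent, else `outside_range`.

`extend_polygon()` reproduces the historical construction that projects
a polygon to larger body sizes: the upper boundary is continued from the
rightmost upper vertex at a given slope (default: the slope of the last
upper-hull edge; the theoretical 2/3 can be passed explicitly — the
historical drawings do not state which was used, so both are exposed),
and a *parallel* lower boundary is drawn through the vertex of minimum
\(\log_{10} E\). Where the historical description is ambiguous about
whether that lower line passes through the minimum-brain vertex or is
tangent elsewhere, the vertex reading is implemented. The union is
re-convexified, which guarantees the original polygon is contained in
the extension whatever slope is supplied.

The extant-reptile points behind the historical reptile polygon are not
published; only the two largest anchors are printed (a 134 kg crocodile,
15.6 g brain; a 205 kg alligator, 14.08 g brain).
`synthetic_reptile_cloud()` therefore generates a documented *synthetic*
stand-in — a 2/3-slope, reptile-grade cloud with those two anchors
appended — so the boundary-classification exercise (an early Paleocene
mammal with a 7.14 ml brain at 16 kg classifying `above` reptile grade)
is testable without the unpublished data. It is labelled synthetic
everywhere and is not the published polygon.

## Surface–volume scaling and convolutedness

`fit_surface_volume()` fits \(\log_{10} S\) on \(\log_{10} E\). A
smooth body scales its surface as volume^(2/3); mammalian *cortical*
surfaces (including cortex buried in sulci) scale much more steeply
(exponent ≈0.9) because larger brains are disproportionately folded.
Endocast surfaces are different: a cast does not enter the sulci, so its
fitted exponent on the packaged table is 0.66 — statistically
indistinguishable from geometric scaling, and a useful caution against
conflating endocast surface with cortical surface. The fitter itself
recovers exact generating laws (e.g. coefficient 3.75, exponent 0.91) to
1e-9, verified in the tests against an independent grid-search
estimator.

`convolutedness_index()` measures folding relative to the dataset's own
smooth trend: a 2/3-pinned reference (`geometric_reference()`, with only
the coefficient fitted, \(c = 10^{\overline{\log_{10}S - \frac23
\log_{10}E}}\)) and the ratio \(S/(c\,E^{2/3})\). The reference is the
dataset's trend, not a sphere, because convolutedness is framed against
brain-size scaling rather than absolute sphericity; the index is linear
in \(S\), equals 1 on the reference curve, and is invariant to the
ordering of the reference data.

## The data model and validation

`read_specimens()` parses the standard CSV schema; blank cells become
`NA`, thousands separators are stripped, and no row is ever silently
dropped — downstream fits each declare the fields they need and report
how many rows they dropped. Three loader conventions worth knowing:

* **Age signs.** A few recent entries are printed with positive ages;
  the loader normalizes fossil-section ages to the negative (millions of
  years *ago*) convention and logs every flip.
* **`OB = 0` vs blank.** Zero means the olfactory bulbs were absent from
  the cast (printed as an explicit 0); blank means not measured. The two
  are kept distinct.
* **Duplicates.** Repeated conspecific rows (two *Daphoenus vetus*, two
  *Hoplophoneus*, …) are separate specimens; nothing is averaged at load
  time.

`validate_specimens()` recomputes every derivable column (%NC, EQ,
additivity \(S = OB + (S{-}OB)\), positivity) and *reports* rather than
raises: transcription is expected to carry the source's own
inconsistencies. On the packaged table, 149/152 percentage cells and
153/154 quotient cells reproduce within the 0.05-point / 0.01
tolerances; the handful of failing cells is pinned as a regression
expectation in the tests, including the known bad *Equus occidentalis*
percentage, which is asserted to *fail*.

The transcription itself carries one known gap: the published table
announces 118 fossil specimens but only 117 fossil rows were recoverable
from the source text available for transcription (the missing row is an
equid referenced in a figure caption). The fixture is verbatim —
nothing was invented to fill the gap — so section counts are
117/22/19.

## Within-species variation

`cv_summary()` and `variation_table()` compute mean, SD and CV per
measurement across conspecific specimens. The SD uses the sample (n−1)
denominator; this is not a style choice but is pinned by the fixture:
the printed SD of the eight conspecific volumes (1.253082) matches the
n−1 formula and not the n formula (≈1.172), and a test asserts exactly
that discrimination. Percentages are printed to one decimal, mirroring
the source's reporting precision; raw statistics are kept at full
precision internally.

## The synthetic generator

`generate_dataset()` draws specimen tables with the statistical
structure the analyses assume, so that parameter recovery can be tested
without any download. Defaults are fixed once, at field-realistic
values, and encode the study conditions rather than tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `n_species` | 200 | comparable to the empirical table's scale |
| `alpha_true`, `log10_b_true` | 2/3, log10(0.12) | the reference allometry |
| `log10P_range` | (2.5, 7) | ≈300 g to 10 t, the table's body-mass span |
| `sd_log10E` | 0.1 | lognormal brain-size residuals of the observed magnitude |
| `age_range_Ma` | (−60, 0) | the Cenozoic window of the empirical data |
| `nc_model` linear | 58% + 0.7·age | present-day ≈58%, ≈15% at −60 Ma |
| `nc_model` saturating | 80·EQ/(0.5+EQ) | Michaelis–Menten shape; simplest curve with the observed ~80% plateau (no functional form is published) |
| `within_species_cv` | 0.10 | the observed conspecific CV |

Surface areas are back-filled self-consistently (bulb-free surface from
volume, neocortex from the percentage, bulbs at 6% of the bulb-free
surface, total surface exactly additive), so every generated record
passes validation with zero fails — a generator-validator consistency
property the tests assert. Generation is seeded and byte-reproducible,
and restores the caller's RNG state.

`generate_within_species()` draws lognormal replicates whose
*distributional* CV equals the target (\(\sigma =
\sqrt{\log(1+cv^2)}\), mean-preserving \(\mu\)). Lognormal rather than
normal keeps every draw positive at any CV; at CV = 0.10 the two are
practically indistinguishable, matching the near-normal appearance of
real conspecific volume series.

What the generator does *not* emulate: phylogenetic autocorrelation (no
trait evolution on trees), measurement covariance between areas and
volumes beyond the deterministic back-fill, taxon-specific intercepts,
and the empirical table's missing-data pattern. Passing recovery tests
therefore show the estimators are correct under the assumed generating
model, not that the historical method is adequate for real,
phylogenetically structured data.

## Numerical choices and test design

* Tolerance comparisons in validation use a 1e-9 epsilon so a
  printed-vs-recomputed gap of *exactly* the tolerance is a pass (strict
  `>` semantics despite binary floats).
* Hull orientation/starting-vertex conventions (above) make vertex
  matrices exactly comparable across runs; geometry tests check the hull
  against an all-pairs \(O(n^3)\) brute-force oracle on seeded
  200-point clouds, and OLS against an independent grid-refinement
  least-squares search (agreement to 1e-6 in slope).
* Statistical tests run at fixed seeds and modest sizes chosen as
  adequate for their tolerances: 100 replicates of 200 species for slope
  recovery (±0.05 in ≥95% of replicates), 10,000 draws for CV recovery
  (±0.005), 200 seeds for the n = 8 CV sampling-distribution band.
* Degenerate inputs error early and by name: nonpositive measurements,
  constant predictors, fewer than three non-collinear points, invalid
  generator configurations.

## Known limitations

* No phylogenetic correction of any kind, by design (see above).
* The %NC-vs-EQ plateau estimate is sensitive to bin width on sparse
  data; on the packaged table it returns `NA` at the defaults.
* The reptile polygon used in boundary tests is a documented synthetic
  stand-in anchored at two printed points, not the published polygon.
* The cortical-surface exponent ≈0.9 belongs to a published regression
  on living-mammal *cortical* surfaces whose underlying 50-species data
  are not in the packaged table; the package exercises it as a
  generating truth for the fitter, never as a quantity reproducible from
  the packaged data.
* One fossil row of the published table is missing from the
  transcription (see above); all counts and fits are over the 158
  recoverable rows.
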