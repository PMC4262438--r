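---
title: "Checking reported p-values against their test statistics"
author: "pchecker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Checking reported p-values against their test statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pchecker)
```

## The problem

An APA-formatted test result — `t(28) = 2.20, p = .036` — is internally
redundant: the statistic and its degrees of freedom determine the
p-value. `pchecker` exploits that redundancy to audit article text for
reporting errors. The pipeline is extraction, recomputation,
rounding-aware comparison, and corpus-level prevalence modelling; each
stage is described here together with the choices that were genuinely
open and how they were resolved.

## Extraction grammar

The scanner matches a single regular grammar per test family: a test
symbol (`t`, `F`, `r`, `Z`, or a χ² spelled `χ2`, `χ²`, `chi2` or
`chi-square`, optionally prefixed `Wald`), a parenthesised degrees-of-
freedom list where the family takes one, a comparator (`=`, `<`, `>`),
the statistic, then — immediately after a comma — `p`, a comparator and
a numeric p-value or `ns`/`n.s.`. Dialect decisions: p-values with or
without a leading zero; decimal degrees of freedom (corrected-df tests
such as Welch or Greenhouse–Geisser print `t(24.3)`); ASCII hyphen or
Unicode minus on negative statistics; `χ²(1, N = 320)` stores the
sample-size annotation without using it (the null distribution needs
only the df); `Wald χ²(df)` and `Wald Z` map onto the two standard Wald
forms, while a bare `Wald = x` has no identifiable null distribution
and is skipped.

Requiring the p-clause to follow the statistic directly is a deliberate
mirror of how such scanners behave on real text: when an effect size is
printed in between (`F(1, 46) = 8.41, η² = .16, p = .006`) the result
is not parsed. These near misses are detected by a second pass with the
statistic-only grammar and returned as *skipped candidates* with offsets
and a reason, so retrieval loss is measurable rather than silent.

Two context heuristics annotate each result. **Sidedness**: manual
coders judge from the whole article whether a test was one-tailed; the
automatable proxy used here is a keyword search ("one-tailed",
"one-sided", "directional") within a character window of the result's
span, measured edge-to-edge. The window is a free parameter, default
200 characters — about two sentences — chosen as the scale over which
such qualifiers plausibly refer to a specific result; there is no
ground truth for this radius, which is why it is exposed as an
argument. **Significance wording**: for results printed `p = .05` the
claimed side of the threshold is unreadable from the number, so the
sentence containing the result (split on `.`, `!`, `?` followed by
whitespace; abbreviation false positives accepted as noise in exchange
for determinism) is searched for negated ("not significant",
"non-significant", "no significant") and plain significance phrases.

Validation excludes what cannot be checked honestly: p-values above 1,
p-values followed by power-of-ten notation (`p = 3.2 × 10⁻⁵`), whose
printed mantissa precision the grammar does not model, and statistics
outside their distribution's support (negative F or χ², |r| > 1).

## Recomputation and rounding

Two-tailed p-values are recomputed for t, r and Z (APA convention for
directional families); F and χ² are inherently upper-tailed. The
correlation uses the standard identity `t = r√(df/(1 − r²))` with
df = n − 2; |r| = 1 returns p = 0 exactly.

A statistic printed with *d* decimals could have been any value within
half a last-digit unit, `h = 0.5·10⁻ᵈ`. Because every supported
family's p is monotone non-increasing in the statistic's magnitude
(verified by grid sweeps in the test suite), evaluating the CDF at the
two endpoints of `[|s| − h, |s| + h]` bounds the recomputed p exactly;
the interval is treated as closed at both ends — immaterial for
continuous distributions but fixed for determinism. When the statistic
itself was reported as an inequality, the matching bound widens to the
distribution's limit. Degenerate cases behave continuously: many
printed decimals collapse the interval to a point; a magnitude below
*h* clips the lower endpoint at zero.

## Classification

The reported p defines an admissible region: `p = v` with *d* decimals
means `[v − h′, v + h′]` with `h′ = 0.5·10⁻ᵈ`; `p < v` is read as the
strict claim `[0, v)` — a one-sided claim carries no rounding band —
and `p > v` as `(v, 1]`; `ns` claims `(α, 1]`; the special print
`p = .000` means `[0, h′)`. A result is consistent when the recomputed
interval overlaps this region. If not, and the result is marked
one-tailed and the family is symmetric (t, r, Z — F and χ² are already
one-tailed), the interval is halved and the overlap re-tested: the
*one-tailed rescue*, applied automatically where human coders would
resolve sidedness case by case.

A gross (decision) error additionally requires the claimed and
recomputed sides of α to disagree. The claimed side comes from the
comparator (`p < v ≤ α` claims significance; `p > v ≥ α` or `ns` claims
nonsignificance; `p = v` claims the side v lies on), with `p = α`
resolved by the sentence wording and otherwise left undetermined — an
undetermined claim can be an error but never a gross error. The
recomputed side is judged by the *whole* interval: the flag is raised
only when every value the true statistic could have had lies on the
opposite side of α, and for one-tailed results the halved interval is
folded in. This conservative rule means statistic rounding can never
manufacture a decision error; it plays the role of the manual
verification step that such flags receive in practice. Whether the
original scanners compared against the point estimate or the interval
is not documented anywhere; the interval rule is this package's own
choice, stated as such.

Tunable parameters, collected: `alpha` (threshold, default 0.05, used
for `ns` regions and gross-error sides), `window` (sidedness radius in
characters, default 200), and the number of decimals is always taken
from the printed token, never assumed.

## The synthetic corpus

Real corpora of journal articles cannot be redistributed, so validation
uses generated articles whose truth is known. The generator emulates
the structure such a study sees: six journals with mean reports per
article from about 8 to 30 (negative-binomial counts, dispersion 5, so
per-journal spread is wide), article counts weighted accordingly
(42/67/107/39/133/42 of 430), a family mix dominated by F and t, a
per-p error probability of 0.106 of which a 0.8/10.6 fraction flips
significance — the operating point reported for real psychology
corpora — and a per-article Normal offset (default SD 1.0) on the
log-odds of error, so errors cluster within articles as they do in
nested data. These defaults were fixed once, from the published
operating point, before any validation was run.

Planted inconsistencies are constructed to be *unambiguous*: the
reported p's rounding band is placed at least two half-widths away from
the recomputed interval, planted decision errors keep the entire
interval (and, for symmetric families, its halved copy) at least one
half-width on the far side of α, and planted non-decision errors keep
both quantities on the same side of α with the same margin. A small
fraction of consistent t/r/Z results is rendered one-tailed (p halved,
"(one-tailed)" appended, with padding text so the keyword cannot leak
into a neighbouring result's window) to exercise the rescue path.
Draws that cannot satisfy the margins are redrawn. Consequently the
checker must recover the planted flags *exactly*, and the truth-table
tests are deterministic rather than probabilistic.

What the generator does not emulate — and therefore what passing tests
do not demonstrate about real articles: publisher layout and PDF
conversion artefacts, effect sizes interleaved inside result strings,
scientific-notation p-values, tables, ambiguous sidedness wording, and
any correlation between error status and the size or direction of the
statistic. The extraction grammar's recall on real text is bounded
above by what it sees here.

## Prevalence models

Article-level rates ("at least one error") use intercept-only logistic
regression; the back-transformed intercept equals the sample proportion
exactly (the IRLS tolerance is tightened to 1e−12 so this identity
holds to numerical precision), and the 95% CI is Wald on the logit
scale, back-transformed. Complete separation (all flags equal) returns
the proportion with a degenerate interval and a warning rather than
failing.

P-value-level rates respect nesting within articles via a
random-intercept logistic model, `flag ~ 1 + (1 | article)`, fitted by
maximum likelihood with adaptive Gauss–Hermite quadrature (default 15
nodes; 1 gives the Laplace approximation, accurate here and used where
many fits are needed). The reported probability is the inverse-logit of
the fixed intercept — conditional on a zero article effect — because
single-number summaries in this literature do not state a
marginalisation; since the population-averaged value differs whenever
the random SD is nonzero, it is also returned
(`marginal_probability`, computed by 40-node Gauss–Hermite integration
of the inverse-logit over the random-effect distribution), and the
random-intercept SD is always reported. Zero estimated variance is a
valid boundary fit, not an error.

Group contrasts (journal, co-piloting indicators coded 1 when two or
more persons were involved, survey response) add the factor as a fixed
effect and use a likelihood-ratio χ² test with df = groups − 1, both
fits under the same approximation; pairwise Wald contrasts are flagged
at α divided by the number of planned tests (a parameter, default 6,
matching a design with six planned comparisons). The conditional
gross-given-error analysis restricts to flagged errors — after
validating that gross ⊆ error — and compares the gross fraction across
groups with the same machinery.

## Numerical choices and degenerate inputs

- Interval endpoints are evaluated, never approximated; endpoint
  inclusion conventions (closed recomputed interval, half-open `<`/`>`
  and `ns` regions, `[0, h′)` for `p = .000`) are fixed and tested by
  brute-force enumeration.
- Equality of a reported p with α is tested to 1e−12 to absorb decimal
  representation error.
- `p = .000`-style prints rounding exactly to the half-width boundary
  depend on round-half-to-even and are excluded from enumeration tests
  rather than legislated.
- Empty documents, empty corpora, unreadable files and empty groups
  degrade explicitly: empty tables, recorded per-file errors, and
  precondition errors respectively; duplicate article ids in metadata
  are a hard error since they would silently misjoin.
- The checker contains no randomness; scanning and classification are
  idempotent, and the generator is byte-identical under a fixed seed.

## Validation scale

The shipped tests run the classifier against a brute-force grid oracle
(step `10^−(d+3)` inside the statistic's rounding interval, region
membership checked directly) on 1,000 randomized reports plus 300 more
in the unit suite; recomputation against quadrature-based tail
probabilities at absolute tolerance 1e−10 on 200 random points per
family; planted-rate recovery on a 500-article corpus with CI coverage
over 50 seeds; multilevel parameter recovery (intercept and
random-effect SD, the latter's standard error obtained from the
numerically differentiated deviance) on a 500-article heterogeneous
corpus; and a full synth → check → prevalence CLI round trip checked
for byte-identical output across runs. These sizes were chosen so the
whole suite completes in a few minutes on one CPU while keeping
Monte-Carlo tolerances meaningful.

## Known limitations

Extraction recall is bounded by APA compliance of the source text;
statistics embedded in tables or with interleaved effect sizes are
counted but not checked. The sidedness window is a heuristic with no
gold standard. `ns` handling and the strict reading of `p < v` are
conventions, stated above, not inferences from any reference
implementation. The multilevel probability is conditional, not
marginal, unless the marginal field is used. And the package checks
internal consistency only: a consistent result can still be wrong, and
an inconsistent one does not say which of statistic, df or p is at
fault.
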