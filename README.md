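# pchecker

Automated consistency checking of statistical results reported in
scientific article text.

Most conclusions in psychology and adjacent fields rest on null
hypothesis significance tests whose results are printed in APA style —
`t(28) = 2.20, p = .036` — which makes them machine-readable: the test
statistic and its degrees of freedom determine the p-value, so a
reported p can be recomputed and checked. Surveys of the literature that
do this find inconsistent p-values in roughly half of articles, some
severe enough to flip the significance decision. `pchecker` is an R
implementation of this checking procedure for researchers studying
reporting quality (meta-scientists, journal editors, methods teachers),
together with the statistical machinery used to summarise error
prevalence across a corpus.

## What it does

For each extracted result with test family t, F, χ², r or Z, the
implied p-value is

- *t*: `p = 2 P(T_df > |t|)`
- *F*: `p = P(F_df1,df2 > F)`
- *χ²*: `p = P(X²_df > χ²)`
- *Z*: `p = 2 Φ(−|Z|)`
- *r*: converted via `t = r √(df / (1 − r²))`, then as *t* with df = n − 2

A statistic printed with *d* decimals stands for any true value within
`h = 0.5·10⁻ᵈ` of the printed number, so the recomputed p is an interval
`[p_lo, p_hi]` (p is monotone in the statistic's magnitude). The
reported p likewise carries its own rounding band. A result is:

- **consistent** — the recomputed interval overlaps the reported band;
- an **error** — no overlap (after attempting a one-tailed rescue, i.e.
  halving, when the text says "one-tailed"/"one-sided"/"directional"
  near the result and the family is symmetric);
- a **gross error** — an error in which the reported side of α = .05 and
  the *entire* recomputed interval disagree, i.e. the inconsistency
  could have changed the significance decision.

Prevalence over a corpus is then estimated exactly as in this
literature: intercept-only logistic regression at the article level
("does the article contain at least one error?") and random-intercept
(multilevel) logistic regression at the p-value level, with
likelihood-ratio tests and Bonferroni-corrected (α/6 for six planned
tests) contrasts for group comparisons such as journal, co-piloting
status or survey response.

Because real journal corpora are copyrighted, the package ships a
synthetic-corpus generator that renders APA results inside filler prose
with a *known* planted error structure (configurable error rate, share
of significance-flipping errors, between-article heterogeneity), used
throughout the tests.

## Worked example

```r
library(pchecker)
snippet <- paste("All two-way interactions were significant:",
                 "A×B, F(1, 20) = 9.5, p<.006; A×C, F(1, 20) = 0.54, p<.03;",
                 "and C×B, F(1, 20) = 6.8, p<.02")
out <- check_text(snippet, "intro")
out$results[, c("family", "df1", "df2", "stat", "p_comp", "p",
                "computed_p", "consistent", "error", "gross_error")]
#>   family df1 df2 stat p_comp     p  computed_p consistent error gross_error
#> 1      F   1  20 9.50     lt 0.006 0.005877146       TRUE FALSE       FALSE
#> 2      F   1  20 0.54     lt 0.030 0.470962119      FALSE  TRUE        TRUE
#> 3      F   1  20 6.80     lt 0.020 0.016844630       TRUE FALSE       FALSE
```

The second result claims `p < .03`, but an F of 0.54 on (1, 20) degrees
of freedom corresponds to p ≈ .47: an inconsistency, and a gross one,
since .47 is on the other side of .05 from the claim. The other two
p-values are compatible with their statistics once rounding is taken
into account.

Corpus-scale use, either programmatically
(`check_corpus()`, `estimate_article_rate()`, `estimate_p_level_rate()`,
`compare_groups()`) or from a shell via the bundled CLI:

```sh
inst/cli/pchecker synth --spec spec.json --out-dir corpus/
inst/cli/pchecker check corpus/*.txt --out-results results.csv --out-articles articles.csv
inst/cli/pchecker prevalence --results results.csv --articles articles.csv --out estimates.json
```

## Limitations

The scanner reads APA-formatted results only: results with effect sizes
or other tokens interleaved between statistic and p-value are skipped
(and counted as skipped candidates), p-values in scientific notation
are flagged as unsupported rather than checked, and PDF conversion is
out of scope — input is plain text or HTML. Sidedness detection is a
keyword heuristic within a configurable character window, not a reading
of the full design. See the methods vignette
(`vignettes/consistency-checking.Rmd`) for the full account of the
procedure, its parameters and its numerical choices.
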