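report_row <- function(family = "t", df1 = 28, df2 = NA_real_, stat = 1.8,
                       stat_dec = 2L, stat_comp = "eq", p_comp = "eq",
                       p = 0.04, p_dec = 2L, one_tailed = FALSE,
                       sig_wording = "unknown") {
  data.frame(article_id = "a", study_id = NA_character_, family = family,
             df1 = df1, df2 = df2, n = NA_integer_, stat_comp = stat_comp,
             stat = stat, stat_dec = stat_dec, p_comp = p_comp, p = p,
             p_dec = p_dec, one_tailed = one_tailed,
             sig_wording = sig_wording, span_start = NA_integer_,
             span_end = NA_integer_, raw = "", post = "",
             stringsAsFactors = FALSE)
}

test_that("reported p regions implement the rounding rule", {
  r <- reported_p_region("eq", 0.03, 2)
  expect_equal(c(r$lo, r$hi), c(0.025, 0.035))
  expect_false(r$lo_open || r$hi_open)

  r <- reported_p_region("lt", 0.05, 2)
  expect_equal(c(r$lo, r$hi), c(0, 0.05))
  expect_true(r$hi_open)

  r <- reported_p_region("gt", 0.1, 1)
  expect_equal(c(r$lo, r$hi), c(0.1, 1))
  expect_true(r$lo_open)

  r <- reported_p_region("ns", NA, NA, alpha = 0.05)
  expect_equal(c(r$lo, r$hi), c(0.05, 1))

  # "p = .000": the limiting case of the rounding band, checked by
  # brute-force rounding enumeration
  r <- reported_p_region("eq", 0, 3)
  expect_equal(c(r$lo, r$hi), c(0, 0.0005))
  expect_true(r$hi_open)
  # enumeration avoids the exact half-width point, where printed output
  # depends on the round-half-to-even convention
  cand <- seq(1e-6, 0.002, by = 7e-6)
  rounds_to_zero <- round(cand, 3) == 0
  inside <- cand >= r$lo & (cand < r$hi)
  expect_equal(inside, rounds_to_zero)

  expect_error(reported_p_region("eq", 1.3, 2), "\\[0, 1\\]")
})

test_that("the worked example classifies as one gross error among three results", {
  txt <- paste("All two-way interactions were significant:",
               "A×B, F(1, 20) = 9.5, p<.006; A×C, F(1, 20) = 0.54, p<.03;",
               "and C×B, F(1, 20) = 6.8, p<.02")
  res <- classify_reports(scan_text(txt, "intro"))
  expect_equal(res$consistent, c(TRUE, FALSE, TRUE))
  expect_equal(res$error, c(FALSE, TRUE, FALSE))
  expect_equal(res$gross_error, c(FALSE, TRUE, FALSE))
  expect_equal(round(res$computed_p[2], 2), 0.47)
})

test_that("exact identities and one-tailed rescue behave as documented", {
  # t = 0 printed with p = 1.00 is internally consistent
  r <- report_row(stat = 0, df1 = 20, p = 1, p_dec = 2L)
  expect_true(classify_report(r)$consistent)

  # t(28) = 1.80 two-tailed p ~ .083; reported .04 one-tailed
  r <- report_row(stat = 1.8, df1 = 28, p = 0.04, one_tailed = TRUE)
  cl <- classify_report(r)
  expect_true(cl$consistent)
  expect_true(cl$one_tailed_applied)
  # without the sidedness flag the same numbers are an error
  r$one_tailed <- FALSE
  cl <- classify_report(r)
  expect_true(cl$error)
  # F is inherently one-tailed: no rescue even when flagged
  rF <- report_row(family = "F", df1 = 1, df2 = 28, stat = 3.24,
                   p = 0.04, one_tailed = TRUE)
  expect_true(classify_report(rF)$error)
  expect_false(classify_report(rF)$one_tailed_applied)
})

test_that("p printed exactly at alpha is resolved by wording and never gross without it", {
  # t(30) = 1.00 -> recomputed ~ .325, far above alpha
  base <- report_row(stat = 1, df1 = 30, p = 0.05, p_dec = 2L)
  cl <- classify_report(base)
  expect_true(cl$error)
  expect_false(cl$gross_error)
  expect_equal(cl$reason, "error_indeterminate_significance")

  sig <- base; sig$sig_wording <- "significant"
  cl <- classify_report(sig)
  expect_true(cl$gross_error)

  nonsig <- base; nonsig$sig_wording <- "nonsignificant"
  cl <- classify_report(nonsig)
  expect_false(cl$gross_error)   # recomputed is also nonsignificant
})

test_that("gross errors require the whole interval on the wrong side of alpha", {
  # t(10) = 2 printed with zero decimals: interval spans p ~ .03 to .17,
  # straddling alpha; the claim p < .001 is an error but cannot be gross
  r <- report_row(stat = 2, df1 = 10, stat_dec = 0L, p_comp = "lt",
                  p = 0.001, p_dec = 3L)
  cl <- classify_report(r)
  expect_true(cl$error)
  expect_false(cl$gross_error)

  # with a precise statistic the same claim is a decision error
  r2 <- report_row(stat = 1.20, df1 = 30, p_comp = "lt", p = 0.001,
                   p_dec = 3L)
  cl2 <- classify_report(r2)
  expect_true(cl2$gross_error)
})

test_that("classifier agrees with the brute-force grid oracle on random reports", {
  set.seed(101)
  reps <- random_reports(300)
  for (i in seq_len(nrow(reps))) {
    r <- reps[i, , drop = FALSE]
    got <- classify_report(r)
    want <- oracle_classify(r)
    expect_equal(got$consistent, want$consistent, info = paste("row", i))
    expect_equal(got$gross_error, want$gross_error, info = paste("row", i))
  }
})

test_that("gross implies error and alpha shifts only affect straddling reports", {
  set.seed(202)
  reps <- random_reports(200)
  res05 <- classify_reports(reps, alpha = 0.05)
  res10 <- classify_reports(reps, alpha = 0.10)
  expect_true(all(!res05$gross_error | res05$error))
  expect_true(all(!res10$gross_error | res10$error))
  changed <- which(res05$gross_error != res10$gross_error)
  for (i in changed) {
    straddles <- (res05$p_lo[i] <= 0.10 && res05$p_hi[i] >= 0.05) ||
      (!is.na(res05$p[i]) && res05$p[i] >= 0.05 && res05$p[i] <= 0.10)
    expect_true(straddles, info = paste("row", i))
  }
})

test_that("classification is deterministic and excludes invalid reports", {
  txt <- paste("We saw t(10) = 8.11, p = 1.3 and also t(12) = 2.20,",
               "p = .04 in the data.")
  r1 <- classify_reports(scan_text(txt, "a"))
  r2 <- classify_reports(scan_text(txt, "a"))
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 1L)
  excluded <- attr(r1, "excluded")
  expect_equal(nrow(excluded), 1L)
  expect_equal(excluded$exclusion, "invalid_p_above_one")
})
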