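snippet <- paste("All two-way interactions were significant:",
                 "A×B, F(1, 20) = 9.5, p<.006; A×C, F(1, 20) = 0.54, p<.03;",
                 "and C×B, F(1, 20) = 6.8, p<.02")

test_that("the three F results of the worked example are extracted", {
  reps <- scan_text(snippet, "intro")
  expect_equal(nrow(reps), 3L)
  expect_equal(reps$family, rep("F", 3))
  expect_equal(reps$df1, rep(1, 3))
  expect_equal(reps$df2, rep(20, 3))
  expect_equal(reps$stat, c(9.5, 0.54, 6.8))
  expect_equal(reps$stat_dec, c(1L, 2L, 1L))
  expect_equal(reps$p_comp, rep("lt", 3))
  expect_equal(reps$p, c(0.006, 0.03, 0.02))
  expect_true(all(diff(reps$span_start) > 0))
})

test_that("empty and result-free documents yield empty tables", {
  expect_equal(nrow(scan_text("", "a")), 0L)
  expect_equal(nrow(scan_text("No numbers in this text at all.", "a")), 0L)
})

test_that("grammar dialects are accepted", {
  cases <- list(
    list(txt = "t(24.3) = 2.15, p = .04", family = "t", df1 = 24.3,
         stat = 2.15, p = 0.04),
    list(txt = "t(28) = -1.80, p = 0.08", family = "t", df1 = 28,
         stat = -1.8, p = 0.08),
    list(txt = "t(28) = −1.80, p = .08", family = "t", df1 = 28,
         stat = -1.8, p = 0.08),              # unicode minus
    list(txt = "F(1,20) = 0.54, p > .05", family = "F", df1 = 1,
         stat = 0.54, p = 0.05),              # no space after comma
    list(txt = "r(30) = .52, p = .002", family = "r", df1 = 30,
         stat = 0.52, p = 0.002),             # no leading zero
    list(txt = "r(30) = -.52, p = .002", family = "r", df1 = 30,
         stat = -0.52, p = 0.002),
    list(txt = "χ2(1, N = 320) = 22.31, p < .001", family = "chi2",
         df1 = 1, stat = 22.31, p = 0.001),
    list(txt = "χ²(4) = 9.11, p = .058", family = "chi2", df1 = 4,
         stat = 9.11, p = 0.058),
    list(txt = "chi2(2) = 5.99, p = .05", family = "chi2", df1 = 2,
         stat = 5.99, p = 0.05),
    list(txt = "chi-square(3) = 7.81, p = .05", family = "chi2", df1 = 3,
         stat = 7.81, p = 0.05),
    list(txt = "Wald χ2(1) = 3.90, p = .048", family = "chi2", df1 = 1,
         stat = 3.9, p = 0.048),
    list(txt = "Wald Z = 2.10, p = .036", family = "Z", df1 = NA_real_,
         stat = 2.1, p = 0.036),
    list(txt = "Z = 1.96, p = .05", family = "Z", df1 = NA_real_,
         stat = 1.96, p = 0.05))
  for (cs in cases) {
    reps <- scan_text(cs$txt, "a")
    expect_equal(nrow(reps), 1L, info = cs$txt)
    expect_equal(reps$family, cs$family, info = cs$txt)
    expect_equal(reps$df1, cs$df1, info = cs$txt)
    expect_equal(reps$stat, cs$stat, info = cs$txt)
    expect_equal(reps$p, cs$p, info = cs$txt)
  }
  # ns variants carry no numeric p
  for (txt in c("t(12) = 1.02, p = ns", "t(12) = 1.02, p = n.s.")) {
    reps <- scan_text(txt, "a")
    expect_equal(reps$p_comp, "ns", info = txt)
    expect_true(is.na(reps$p), info = txt)
  }
  # chi2 N annotation is stored but df drives everything
  reps <- scan_text("χ2(1, N = 4,210) = 22.31, p < .001", "a")
  expect_equal(reps$n, 4210L)
})

test_that("results with tokens between statistic and p are skipped with a diagnostic", {
  txt <- "A main effect emerged, F(1, 46) = 8.41, η2 = .16, p = .006."
  reps <- scan_text(txt, "a")
  expect_equal(nrow(reps), 0L)
  skipped <- attr(reps, "skipped")
  expect_equal(nrow(skipped), 1L)
  expect_equal(skipped$reason, "tokens_between_statistic_and_p")
  # a bare Wald with no distribution form is not parseable either
  reps2 <- scan_text("Wald = 3.2, p = .07", "a")
  expect_equal(nrow(reps2), 0L)
})

test_that("scanning is idempotent and offsets recover the raw spans", {
  r1 <- scan_text(snippet, "a")
  r2 <- scan_text(snippet, "a")
  expect_identical(r1, r2)
  for (i in seq_len(nrow(r1))) {
    expect_equal(substr(snippet, r1$span_start[i], r1$span_end[i]),
                 r1$raw[i])
  }
})

test_that("sidedness detection honours the character window exactly", {
  txt <- "We report t(28) = 1.80, p = .04 (one-tailed) in study 1."
  reps <- scan_text(txt, "a")
  expect_true(reps$one_tailed)
  expect_false(detect_sidedness("t(28) = 1.80, p = .04 and nothing else",
                                15, 36, 200))
  # keyword placed at an exact distance from the span end
  for (gap in c(0, 50, 200, 201, 300)) {
    txt2 <- paste0(strrep("x", 10), "SPAN", strrep(" ", gap), "one-tailed")
    # span: characters 11..14
    expect_equal(detect_sidedness(txt2, 11, 14, 200), gap + 1 <= 200,
                 info = paste("gap", gap))
  }
})

test_that("significance wording is read from the containing sentence", {
  expect_equal(detect_sig_wording(
    "The effect was significant, F(1, 46) = 4.20, p = .05.", 29, 52),
    "significant")
  expect_equal(detect_sig_wording(
    "The difference was not significant, t(30) = 1.2, p = .24.", 37, 57),
    "nonsignificant")
  expect_equal(detect_sig_wording(
    "We observed t(30) = 1.2, p = .24.", 13, 32), "unknown")
  # wording in a neighbouring sentence does not leak
  txt <- "The first test was significant. We then saw t(30) = 1.2, p = .24."
  reps <- scan_text(txt, "a")
  expect_equal(reps$sig_wording, "unknown")
  # negation variants
  for (w in c("non-significant", "nonsignificant", "no significant")) {
    txt2 <- sprintf("There was %s change, t(30) = 1.2, p = .24.", w)
    reps2 <- scan_text(txt2, "a")
    expect_equal(reps2$sig_wording, "nonsignificant", info = w)
  }
})

test_that("validation excludes p > 1 and power-of-ten notation", {
  r <- scan_text("t(10) = 8.11, p = 1.3", "a")
  expect_equal(validate_report(r), "invalid_p_above_one")
  r <- scan_text("t(10) = 8.11, p = 3.2 × 10−5 overall", "a")
  expect_equal(validate_report(r), "unsupported_notation")
  r <- scan_text("t(10) = 8.11, p = 3.2e-5 overall", "a")
  expect_equal(validate_report(r), "unsupported_notation")
  r <- scan_text("t(10) = 2.11, p = .03", "a")
  expect_equal(validate_report(r), "valid")
  r <- scan_text("r(30) = 1.52, p = .03", "a")
  expect_equal(validate_report(r), "invalid_statistic")
})

test_that("HTML is stripped to scannable text", {
  html <- "<html><body><p>We found <i>t</i>(28) = 2.20, p = .036.</p></body></html>"
  reps <- scan_text(strip_html(html), "a")
  expect_equal(nrow(reps), 1L)
  expect_equal(reps$stat, 2.2)
})
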