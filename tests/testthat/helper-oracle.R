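# Independent oracles used across the suite.
#
# oracle_tail_p: tail probabilities by numerical integration of the null
# density (quadrature route, independent of the distribution-function
# route used by the package).
#
# oracle_classify: brute-force consistency verdict by enumerating a dense
# grid of true statistic values inside the printed statistic's rounding
# interval and testing reported-region membership directly, with no use
# of interval endpoints or monotonicity.

oracle_tail_p <- function(family, stat, df1 = NA, df2 = NA) {
  tol <- list(rel.tol = 1e-13, abs.tol = 1e-14)
  upper_tail <- function(dens, from) {
    do.call(stats::integrate,
            c(list(dens, lower = from, upper = Inf), tol))$value
  }
  switch(family,
    t = 2 * upper_tail(function(x) stats::dt(x, df1), abs(stat)),
    F = upper_tail(function(x) stats::df(x, df1, df2), stat),
    chi2 = upper_tail(function(x) stats::dchisq(x, df1), stat),
    Z = 2 * upper_tail(stats::dnorm, abs(stat)),
    r = {
      if (abs(stat) >= 1) return(0)
      tv <- abs(stat) * sqrt(df1 / (1 - stat^2))
      2 * upper_tail(function(x) stats::dt(x, df1), tv)
    })
}

# membership of a recomputed p in the region claimed by the report
oracle_member <- function(p, p_comp, p_rep, p_dec, alpha = 0.05) {
  switch(p_comp,
    eq = {
      h <- 0.5 * 10^(-p_dec)
      if (p_rep == 0) p < h else (p >= p_rep - h & p <= p_rep + h)
    },
    lt = p < p_rep,
    gt = p > p_rep,
    ns = p > alpha)
}

oracle_classify <- function(report, alpha = 0.05) {
  d <- report$stat_dec
  h <- 0.5 * 10^(-d)
  a <- abs(report$stat)
  lo <- max(a - h, 0)
  hi <- a + h
  if (report$family == "r") hi <- min(hi, 1)
  grid <- unique(c(seq(lo, hi, by = 10^(-(d + 3))), lo, hi))
  ps <- computed_p(report$family, grid, report$df1, report$df2)

  member <- oracle_member(ps, report$p_comp, report$p, report$p_dec, alpha)
  consistent <- any(member)
  one_tailed_applied <- FALSE
  symmetric <- report$family %in% c("t", "r", "Z")
  halved <- isTRUE(report$one_tailed) && symmetric
  if (!consistent && halved) {
    member2 <- oracle_member(ps / 2, report$p_comp, report$p,
                             report$p_dec, alpha)
    if (any(member2)) {
      consistent <- TRUE
      one_tailed_applied <- TRUE
    }
  }
  error <- !consistent

  pc <- report$p_comp; pv <- report$p; w <- report$sig_wording
  rep_sig <- NA
  if (pc == "lt" && pv <= alpha) rep_sig <- TRUE
  else if (pc == "ns") rep_sig <- FALSE
  else if (pc == "gt" && pv >= alpha) rep_sig <- FALSE
  else if (pc == "eq") {
    if (abs(pv - alpha) < 1e-12) {
      if (identical(w, "significant")) rep_sig <- TRUE
      else if (identical(w, "nonsignificant")) rep_sig <- FALSE
    } else rep_sig <- pv < alpha
  }
  all_vals <- if (halved) c(ps, ps / 2) else ps
  gross <- error && !is.na(rep_sig) &&
    ((isTRUE(rep_sig) && all(all_vals > alpha)) ||
     (isFALSE(rep_sig) && all(all_vals < alpha)))
  list(consistent = consistent, error = error, gross_error = gross,
       one_tailed_applied = one_tailed_applied)
}

# Randomized report rows (independent of the synthetic-corpus module):
# a deliberate mix of consistent, near-boundary and clearly inconsistent
# reports across families, comparators and sidedness.
random_reports <- function(n) {
  fams <- c("t", "F", "chi2", "r", "Z")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    family <- sample(fams, 1)
    df1 <- switch(family, t = sample(5:150, 1), F = sample(1:5, 1),
                  chi2 = sample(1:10, 1), r = sample(10:200, 1),
                  Z = NA_real_)
    df2 <- if (family == "F") sample(10:200, 1) else NA_real_
    stat_dec <- sample(1:3, 1)
    stat <- switch(family,
      t = round(stats::runif(1, 0, 4) * sample(c(-1, 1), 1), stat_dec),
      F = round(stats::runif(1, 0, 12), stat_dec),
      chi2 = round(stats::runif(1, 0, 25), stat_dec),
      r = round(stats::runif(1, -0.95, 0.95), stat_dec),
      Z = round(stats::runif(1, 0, 4) * sample(c(-1, 1), 1), stat_dec))
    p_mid <- computed_p(family, stat, df1, df2)
    p_dec <- sample(2:3, 1)
    kind <- sample(c("match", "jitter", "far", "boundary"), 1,
                   prob = c(0.4, 0.25, 0.25, 0.1))
    p_rep <- switch(kind,
      match = round(p_mid, p_dec),
      jitter = round(min(max(p_mid + stats::runif(1, -0.02, 0.02), 0), 1),
                     p_dec),
      far = round(stats::runif(1), p_dec),
      boundary = 0.05)
    p_comp <- sample(c("eq", "lt", "gt", "ns"), 1,
                     prob = c(0.8, 0.1, 0.05, 0.05))
    if (p_comp == "ns") { p_rep <- NA_real_; p_dec <- NA_integer_ }
    one_tailed <- family %in% c("t", "r", "Z") && stats::runif(1) < 0.15
    wording <- sample(c("significant", "nonsignificant", "unknown"), 1,
                      prob = c(0.25, 0.15, 0.6))
    out[[i]] <- data.frame(
      article_id = sprintf("rnd%04d", i), study_id = NA_character_,
      family = family, df1 = df1, df2 = df2, n = NA_integer_,
      stat_comp = "eq", stat = stat, stat_dec = stat_dec,
      p_comp = p_comp, p = p_rep, p_dec = p_dec,
      one_tailed = one_tailed, sig_wording = wording,
      span_start = NA_integer_, span_end = NA_integer_,
      raw = "", post = "", stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
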