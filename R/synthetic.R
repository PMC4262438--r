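# Synthetic article corpus with planted reporting errors -----------------
#
# Stands in for a real journal corpus: articles are filler prose carrying
# APA-formatted results whose consistency status is known by construction.
# Planted inconsistencies are placed at least two rounding half-widths
# away from the consistency region, and planted decision (gross) errors
# keep the whole recomputed interval on one side of alpha, so the checker
# must recover the planted truth exactly rather than probabilistically.

#' Specification of a synthetic corpus
#'
#' Defaults emulate a six-journal psychology corpus: per-journal mean
#' reports per article from about 8 to 30 with article counts weighted
#' accordingly, an overall per-p-value inconsistency rate of 10.6% of
#' which about 7.5% are significance-flipping, and between-article
#' heterogeneity on the log-odds of error.
#'
#' @param n_articles number of articles (default 430).
#' @param journal_means named numeric: mean reports per article per journal.
#' @param journal_weights article-count weights, same length as
#'   \code{journal_means}.
#' @param dispersion negative-binomial size parameter for the
#'   reports-per-article count (smaller = more overdispersed).
#' @param family_mix named probability vector over t, F, chi2, r, Z.
#' @param error_rate probability that a reported p is planted inconsistent.
#' @param gross_fraction fraction of planted errors forced across the
#'   significance threshold.
#' @param article_effect_sd SD of the per-article Normal offset on the
#'   log-odds of error (0 = homogeneous articles).
#' @param one_tailed_rate fraction of consistent t/r/Z results rendered as
#'   one-tailed (p halved, "(one-tailed)" appended) to exercise the
#'   one-tailed rescue.
#' @param seed integer seed; fixed seed gives byte-identical corpora.
#' @return a list of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(n_articles = 430,
                           journal_means = c(JAP = 8.10, JCCP = 12.43,
                                             JCN = 16.08, JCPP = 11.38,
                                             JPSP = 30.21, PP = 17.83),
                           journal_weights = c(42, 67, 107, 39, 133, 42),
                           dispersion = 5,
                           family_mix = c(t = 0.30, F = 0.45, chi2 = 0.10,
                                          r = 0.10, Z = 0.05),
                           error_rate = 0.106,
                           gross_fraction = 0.8 / 10.6,
                           article_effect_sd = 1.0,
                           one_tailed_rate = 0.02,
                           seed = 1L) {
  stopifnot(n_articles >= 1,
            length(journal_means) == length(journal_weights),
            all(journal_weights > 0),
            abs(sum(family_mix) - 1) < 1e-8,
            all(family_mix >= 0),
            error_rate >= 0, error_rate <= 1,
            gross_fraction >= 0, gross_fraction <= 1,
            article_effect_sd >= 0,
            one_tailed_rate >= 0, one_tailed_rate <= 1,
            dispersion > 0)
  structure(list(n_articles = as.integer(n_articles),
                 journal_means = journal_means,
                 journal_weights = journal_weights,
                 dispersion = dispersion, family_mix = family_mix,
                 error_rate = error_rate, gross_fraction = gross_fraction,
                 article_effect_sd = article_effect_sd,
                 one_tailed_rate = one_tailed_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(paste0("synthetic corpus spec: %d articles, %d journals, ",
                     "error rate %.3f (gross fraction %.3f), ",
                     "article effect sd %.2f, seed %d\n"),
              x$n_articles, length(x$journal_means), x$error_rate,
              x$gross_fraction, x$article_effect_sd, x$seed))
  invisible(x)
}

.fmt_df <- function(x) {
  if (abs(x - round(x)) < 1e-9) sprintf("%d", as.integer(round(x)))
  else sub("0+$", "", sprintf("%.4f", x))
}

.fmt_stat <- function(family, stat, dec) {
  s <- sprintf("%.*f", dec, stat)
  if (family == "r") s <- sub("^(-?)0\\.", "\\1.", s)
  s
}

.fmt_p <- function(p, dec) sub("^0\\.", ".", sprintf("%.*f", dec, p))

#' Render a report in canonical APA text
#'
#' Inverse of [scan_text()] on the field level: a rescanned emission
#' recovers every field exactly.
#'
#' @param report one row with columns \code{family, df1, df2, n, stat,
#'   stat_dec, stat_comp, p_comp, p, p_dec}.
#' @return a character scalar like \code{"F(1, 20) = 0.54, p < .03"}.
#' @examples
#' emit_apa(data.frame(family = "t", df1 = 28, df2 = NA, n = NA,
#'                     stat = 1.8, stat_dec = 2, stat_comp = "eq",
#'                     p_comp = "eq", p = 0.04, p_dec = 2))
#' @export
emit_apa <- function(report) {
  stopifnot(nrow(report) == 1L)
  .emit_apa_fields(report$family, report$df1, report$df2, report$n,
                   report$stat, report$stat_dec, report$stat_comp,
                   report$p_comp, report$p, report$p_dec)
}

.emit_apa_fields <- function(family, df1, df2, n, stat, stat_dec,
                             stat_comp, p_comp, p, p_dec) {
  comp <- c(eq = "=", lt = "<", gt = ">")
  head <- switch(family,
    t = sprintf("t(%s)", .fmt_df(df1)),
    F = sprintf("F(%s, %s)", .fmt_df(df1), .fmt_df(df2)),
    r = sprintf("r(%s)", .fmt_df(df1)),
    chi2 = if (!is.na(n)) sprintf("χ2(%s, N = %d)", .fmt_df(df1), n)
           else sprintf("χ2(%s)", .fmt_df(df1)),
    Z = "Z")
  stat_s <- .fmt_stat(family, stat, stat_dec)
  p_s <- if (p_comp == "ns") "p = ns"
    else sprintf("p %s %s", comp[[p_comp]], .fmt_p(p, p_dec))
  sprintf("%s %s %s, %s", head, comp[[stat_comp]], stat_s, p_s)
}

# degrees of freedom and sign conventions per family
.draw_shape <- function(family) {
  sh <- switch(family,
    t = list(df1 = sample(8:120, 1), df2 = NA_real_),
    F = list(df1 = sample(1:4, 1), df2 = sample(12:150, 1)),
    chi2 = list(df1 = sample(1:8, 1), df2 = NA_real_),
    r = list(df1 = sample(20:200, 1), df2 = NA_real_),
    Z = list(df1 = NA_real_, df2 = NA_real_))
  sh$n <- if (family == "chi2" && stats::runif(1) < 0.5)
    sample(30:500, 1) else NA_integer_
  sh
}

# statistic whose exact p equals p_true, before printing/rounding
.stat_for_p <- function(family, p_true, df1, df2) {
  switch(family,
    t = stats::qt(1 - p_true / 2, df1),
    F = stats::qf(1 - p_true, df1, df2),
    chi2 = stats::qchisq(1 - p_true, df1),
    Z = stats::qnorm(1 - p_true / 2),
    r = {
      tv <- stats::qt(1 - p_true / 2, df1)
      tv / sqrt(tv^2 + df1)
    })
}

# Draw one report + its planted truth. Returns NULL when the draw cannot
# satisfy the unambiguity margins (caller redraws).
.draw_report <- function(family, err, gross, one_tailed_rate, alpha = 0.05) {
  sh <- .draw_shape(family)
  stat_dec <- 2L
  h_stat <- 0.5 * 10^(-stat_dec)

  if (!err) {
    p_true <- 10^stats::runif(1, log10(5e-4), log10(0.95))
  } else if (gross) {
    flip_up <- stats::runif(1) < 0.5   # true nonsig, reported sig
    p_true <- if (flip_up) stats::runif(1, 0.15, 0.90)
              else stats::runif(1, 5e-4, 0.015)
  } else {
    same_nonsig <- stats::runif(1) < 0.5
    p_true <- if (same_nonsig) stats::runif(1, 0.30, 0.90)
              else stats::runif(1, 1e-4, 0.004)
  }

  stat <- .stat_for_p(family, p_true, sh$df1, sh$df2)
  if (family %in% c("t", "r", "Z") && stats::runif(1) < 0.3) stat <- -stat
  stat <- round(stat, stat_dec)
  if (family == "r" && abs(stat) >= 1) return(NULL)
  if (family %in% c("F", "chi2") && stat < h_stat) return(NULL)
  iv <- p_interval(family, stat, stat_dec, df1 = sh$df1, df2 = sh$df2)

  one_tailed <- FALSE
  if (!err) {
    p_dec <- sample(2:3, 1)
    hp <- 0.5 * 10^(-p_dec)
    if (family %in% c("t", "r", "Z") &&
        stats::runif(1) < one_tailed_rate) {
      p_rep <- round(iv$p_mid / 2, p_dec)
      two_sided_region <- reported_p_region("eq", p_rep, p_dec, alpha)
      ok <- p_rep > 0 && abs(p_rep - alpha) > 1e-9 &&
        !.overlaps(iv$p_lo, iv$p_hi, two_sided_region)
      if (ok) {
        return(list(df1 = sh$df1, df2 = sh$df2, n = sh$n,
                    stat = stat, stat_dec = stat_dec, stat_comp = "eq",
                    p_comp = "eq", p = p_rep, p_dec = p_dec,
                    one_tailed = TRUE, is_error = FALSE, is_gross = FALSE))
      }
    }
    if (iv$p_mid < 0.001) {
      p_comp <- "lt"; p_rep <- 0.001; p_dec <- 3L
    } else if (stats::runif(1) < 0.05 && iv$p_lo > alpha + 0.02) {
      p_comp <- "ns"; p_rep <- NA_real_; p_dec <- NA_integer_
    } else {
      p_comp <- "eq"
      p_rep <- round(iv$p_mid, p_dec)
      if (abs(p_rep - alpha) < 1e-9) {
        p_dec <- 3L
        p_rep <- round(iv$p_mid, p_dec)
        if (abs(p_rep - alpha) < 1e-9) return(NULL)
      }
    }
    return(list(df1 = sh$df1, df2 = sh$df2, n = sh$n,
                stat = stat, stat_dec = stat_dec, stat_comp = "eq",
                p_comp = p_comp, p = p_rep, p_dec = p_dec,
                one_tailed = one_tailed, is_error = FALSE,
                is_gross = FALSE))
  }

  # planted inconsistency: choose the reported p, then verify margins
  if (gross) {
    flip_up <- iv$p_lo > alpha   # recomputed nonsig -> report significant
    if (flip_up) {
      p_dec <- 2L
      p_rep <- sample(c(0.01, 0.02, 0.03, 0.04), 1)
    } else {
      p_dec <- 2L
      p_rep <- round(stats::runif(1, 0.20, 0.80), p_dec)
    }
  } else {
    same_nonsig <- iv$p_mid > alpha
    if (same_nonsig) {
      p_dec <- 2L
      p_rep <- round(stats::runif(1, 0.07, 0.20), p_dec)
    } else {
      p_dec <- 3L
      p_rep <- round(stats::runif(1, 0.020, 0.045), p_dec)
    }
  }
  hp <- 0.5 * 10^(-p_dec)
  # unambiguous inconsistency: region at least 2 half-widths from interval
  gap_ok <- (iv$p_lo - (p_rep + hp) >= 2 * hp) ||
            ((p_rep - hp) - iv$p_hi >= 2 * hp)
  if (!gap_ok) return(NULL)
  if (gross) {
    side_ok <- if (p_rep < alpha) iv$p_lo > alpha + hp
               else iv$p_hi < alpha - hp
    claim_ok <- if (p_rep < alpha) (p_rep + hp) < alpha
                else (p_rep - hp) > alpha
    if (!side_ok || !claim_ok) return(NULL)
  } else {
    # same side of alpha, with margin, so no decision flip is possible
    both_nonsig <- iv$p_lo > alpha + hp && (p_rep - hp) > alpha
    both_sig <- iv$p_hi < alpha - hp && (p_rep + hp) < alpha
    if (!both_nonsig && !both_sig) return(NULL)
  }
  if (family %in% c("t", "r", "Z")) {
    # stay unambiguous even under a (spurious) one-tailed reading:
    # the halved interval must not rescue, and a planted decision error
    # must survive the conservative folded-interval rule
    region <- reported_p_region("eq", p_rep, p_dec, alpha)
    if (.overlaps(iv$p_lo / 2, iv$p_hi / 2, region)) return(NULL)
    if (gross && p_rep < alpha && !(iv$p_lo / 2 > alpha + hp)) return(NULL)
  }
  list(df1 = sh$df1, df2 = sh$df2, n = sh$n,
       stat = stat, stat_dec = stat_dec, stat_comp = "eq",
       p_comp = "eq", p = p_rep, p_dec = p_dec,
       one_tailed = FALSE, is_error = TRUE, is_gross = gross)
}

.pad_sentence <- paste(
  "Additional procedural detail, counterbalancing notes, apparatus",
  "description, exclusion rules and the full preregistered analysis plan",
  "for this comparison appear in the supplementary materials accompanying",
  "this report and are not repeated in the running text of this section.")

.filler <- c(
  "The main effect of condition %d was evident in the omnibus analysis, %s.",
  "Planned contrast %d pointed in the expected direction, %s.",
  "For outcome %d the model term was retained, %s.",
  "Follow-up analysis %d gave %s.",
  "The interaction in block %d was appreciable, %s.",
  "Replicating study %d, we observed %s.")

#' Generate a synthetic corpus with planted errors
#'
#' For each article a journal is drawn by weight, a report count from a
#' negative-binomial with that journal's mean, and an article-level offset
#' on the log-odds of error from Normal(0, \code{article_effect_sd}).
#' Each report draws a family, plausible degrees of freedom and a test
#' statistic; with probability \code{plogis(qlogis(error_rate) + offset)}
#' the reported p is perturbed into a planted inconsistency (a
#' \code{gross_fraction} share of which flips significance). Reports are
#' rendered in APA style inside filler prose.
#'
#' @param spec a [synthetic_spec()].
#' @return list with \code{texts} (named character vector, one article
#'   per element), \code{truth} (per-report ground-truth table with
#'   \code{is_error}, \code{is_gross}) and \code{articles}
#'   (\code{article_id}, \code{journal}, \code{logit_offset}).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  journals <- names(spec$journal_means)
  art_journal <- sample(journals, spec$n_articles, replace = TRUE,
                        prob = spec$journal_weights)
  fams <- names(spec$family_mix)

  texts <- character(spec$n_articles)
  ids <- sprintf("art%04d", seq_len(spec$n_articles))
  offsets <- stats::rnorm(spec$n_articles, 0, spec$article_effect_sd)
  truth <- vector("list", spec$n_articles)

  base_logit <- stats::qlogis(spec$error_rate)
  for (a in seq_len(spec$n_articles)) {
    mu <- spec$journal_means[[art_journal[a]]]
    n_rep <- max(1L, stats::rnbinom(1, size = spec$dispersion, mu = mu))
    p_err <- stats::plogis(base_logit + offsets[a])

    rows <- vector("list", n_rep)
    sentences <- character(n_rep)
    for (j in seq_len(n_rep)) {
      family <- sample(fams, 1, prob = spec$family_mix)
      err <- stats::runif(1) < p_err
      gross <- err && stats::runif(1) < spec$gross_fraction
      rep_j <- NULL
      for (try in 1:100) {
        rep_j <- .draw_report(family, err, gross, spec$one_tailed_rate)
        if (!is.null(rep_j)) break
      }
      if (is.null(rep_j)) {   # pathological corner: fall back to consistent
        err <- FALSE; gross <- FALSE
        while (is.null(rep_j)) {
          rep_j <- .draw_report(family, FALSE, FALSE, 0)
        }
      }
      rep_j$family <- family
      rep_j$report_idx <- j
      rows[[j]] <- rep_j
      apa <- .emit_apa_fields(rep_j$family, rep_j$df1, rep_j$df2, rep_j$n,
                              rep_j$stat, rep_j$stat_dec, rep_j$stat_comp,
                              rep_j$p_comp, rep_j$p, rep_j$p_dec)
      if (rep_j$one_tailed) apa <- paste0(apa, " (one-tailed)")
      sentences[j] <- sprintf(sample(.filler, 1), j, apa)
      if (rep_j$one_tailed) {
        # keep the sidedness keyword out of neighbouring results' windows
        sentences[j] <- paste(.pad_sentence, sentences[j], .pad_sentence)
      }
    }
    pull <- function(field, template) {
      vapply(rows, function(r) r[[field]], template)
    }
    truth[[a]] <- data.frame(
      article_id = ids[a], journal = art_journal[a],
      report_idx = pull("report_idx", integer(1)),
      family = pull("family", character(1)),
      df1 = pull("df1", numeric(1)), df2 = as.numeric(pull("df2", numeric(1))),
      n = pull("n", integer(1)),
      stat_comp = pull("stat_comp", character(1)),
      stat = pull("stat", numeric(1)),
      stat_dec = pull("stat_dec", integer(1)),
      p_comp = pull("p_comp", character(1)),
      p = pull("p", numeric(1)), p_dec = pull("p_dec", integer(1)),
      one_tailed = pull("one_tailed", logical(1)),
      is_error = pull("is_error", logical(1)),
      is_gross = pull("is_gross", logical(1)),
      stringsAsFactors = FALSE)
    texts[a] <- paste(
      c(sprintf("Study report %s.", ids[a]), sentences,
        "Further descriptive detail is omitted here."),
      collapse = " ")
  }
  list(texts = stats::setNames(texts, ids),
       truth = do.call(rbind, c(truth, make.row.names = FALSE)),
       articles = data.frame(article_id = ids, journal = art_journal,
                             logit_offset = offsets,
                             stringsAsFactors = FALSE))
}

#' Write a generated corpus to disk
#'
#' One \code{<article_id>.txt} per article plus a \code{truth.csv}.
#'
#' @param corpus result of [generate_corpus()].
#' @param out_dir directory for article files (created if needed).
#' @param truth_path path for the ground-truth CSV.
#' @return invisibly, the vector of file paths written.
#' @export
write_corpus <- function(corpus, out_dir, truth_path = file.path(out_dir, "truth.csv")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, paste0(names(corpus$texts), ".txt"))
  for (i in seq_along(paths)) {
    writeLines(corpus$texts[[i]], paths[i], useBytes = TRUE)
  }
  utils::write.csv(corpus$truth, truth_path, row.names = FALSE)
  invisible(paths)
}
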