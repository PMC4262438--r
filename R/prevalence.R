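# Prevalence estimation: intercept-only and multilevel logistic ----------

.logit_ci <- function(est, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  stats::plogis(c(est - z * se, est + z * se))
}

#' Article-level prevalence via intercept-only logistic regression
#'
#' Fits \code{flag ~ 1} by maximum-likelihood logistic regression. The
#' back-transformed intercept equals the sample proportion exactly; the
#' 95% confidence interval is Wald on the logit scale, back-transformed.
#' All-true or all-false input is complete separation: the proportion is
#' returned with a degenerate interval and a warning instead of a failure.
#'
#' @param any_flags logical vector (e.g. "article contains at least one
#'   inconsistent p-value").
#' @param level confidence level (default 0.95).
#' @return list of class \code{"corpus_estimate"}: \code{probability},
#'   \code{ci_lo}, \code{ci_hi}, \code{model = "simple_logit"}, \code{n}.
#' @examples
#' estimate_article_rate(c(rep(TRUE, 63), rep(FALSE, 37)))
#' @export
estimate_article_rate <- function(any_flags, level = 0.95) {
  any_flags <- as.logical(any_flags)
  stopifnot(length(any_flags) >= 1, !anyNA(any_flags))
  n <- length(any_flags)
  prop <- mean(any_flags)
  if (prop %in% c(0, 1)) {
    warning("complete separation: all flags identical; degenerate CI")
    est <- list(probability = prop, ci_lo = prop, ci_hi = prop,
                model = "simple_logit", random_intercept_sd = NA_real_,
                n = n)
    class(est) <- "corpus_estimate"
    return(est)
  }
  fit <- stats::glm(any_flags ~ 1, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12))
  b <- unname(stats::coef(fit)[1])
  se <- sqrt(stats::vcov(fit)[1, 1])
  ci <- .logit_ci(b, se, level)
  est <- list(probability = unname(stats::plogis(b)), ci_lo = ci[1],
              ci_hi = ci[2], model = "simple_logit",
              random_intercept_sd = NA_real_, n = n)
  class(est) <- "corpus_estimate"
  est
}

#' @export
print.corpus_estimate <- function(x, ...) {
  cat(sprintf("%s: probability %.3f (95%% CI %.3f-%.3f), n = %d",
              x$model, x$probability, x$ci_lo, x$ci_hi, x$n))
  if (!is.na(x$random_intercept_sd)) {
    cat(sprintf(", random intercept sd %.3f", x$random_intercept_sd))
  }
  cat("\n")
  invisible(x)
}

#' P-value-level prevalence via random-intercept logistic regression
#'
#' P-values are nested within articles, so the per-p-value error
#' probability is estimated with a multilevel logistic model with article
#' as a random factor: \code{flag ~ 1 + (1 | article)}, fitted by maximum
#' likelihood with adaptive Gauss-Hermite quadrature over the article
#' intercepts. The reported probability is the inverse-logit of the fixed
#' intercept (conditional on a zero random effect), with a Wald interval
#' on the logit scale; the population-averaged (marginal) probability,
#' which integrates the random effect out, is also returned since the two
#' differ whenever the random-intercept SD is nonzero.
#'
#' @param flags logical vector, one per p-value.
#' @param article_ids article identifier per flag (>= 2 distinct).
#' @param nAGQ number of adaptive Gauss-Hermite quadrature nodes
#'   (default 15; 1 = Laplace approximation).
#' @param level confidence level.
#' @return list of class \code{"corpus_estimate"} with
#'   \code{probability}, \code{ci_lo}, \code{ci_hi},
#'   \code{model = "multilevel_logit"}, \code{random_intercept_sd},
#'   \code{marginal_probability}, \code{intercept}, \code{intercept_se},
#'   \code{n}, \code{n_articles}, \code{converged}.
#' @export
estimate_p_level_rate <- function(flags, article_ids, nAGQ = 15,
                                  level = 0.95) {
  flags <- as.logical(flags)
  stopifnot(length(flags) == length(article_ids), !anyNA(flags))
  if (length(unique(article_ids)) < 2) {
    stop("need at least 2 distinct articles for a multilevel fit")
  }
  if (all(flags) || !any(flags)) {
    warning("complete separation: all flags identical; degenerate CI")
    prop <- mean(flags)
    est <- list(probability = prop, ci_lo = prop, ci_hi = prop,
                model = "multilevel_logit", random_intercept_sd = 0,
                marginal_probability = prop, intercept = stats::qlogis(prop),
                intercept_se = NA_real_, n = length(flags),
                n_articles = length(unique(article_ids)), converged = TRUE)
    class(est) <- "corpus_estimate"
    return(est)
  }
  dat <- data.frame(y = flags, article = factor(article_ids))
  fit <- lme4::glmer(y ~ 1 + (1 | article), data = dat,
                     family = stats::binomial(), nAGQ = nAGQ)
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  b <- unname(lme4::fixef(fit)[1])
  se <- sqrt(as.matrix(stats::vcov(fit))[1, 1])
  sd_re <- sqrt(unname(lme4::VarCorr(fit)$article[1, 1]))
  ci <- .logit_ci(b, se, level)
  # population-averaged probability: integrate logistic over N(0, sd^2)
  gh <- .gauss_hermite(40)
  marg <- sum(gh$w * stats::plogis(b + sqrt(2) * sd_re * gh$x)) / sqrt(pi)
  est <- list(probability = unname(stats::plogis(b)), ci_lo = ci[1],
              ci_hi = ci[2], model = "multilevel_logit",
              random_intercept_sd = sd_re, marginal_probability = marg,
              intercept = b, intercept_se = se, n = nrow(dat),
              n_articles = nlevels(dat$article), converged = conv,
              fit = fit)
  class(est) <- "corpus_estimate"
  est
}

# Gauss-Hermite nodes/weights via the Golub-Welsch eigendecomposition
.gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- sqrt(i / 2)
  J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

#' Compare error prevalence between groups with a Bonferroni-corrected
#' multilevel model
#'
#' Adds the grouping factor (journal, a co-piloting indicator, survey
#' response, ...) as a fixed factor to the random-intercept logistic model
#' and tests it with a likelihood-ratio chi-squared test
#' (df = groups - 1). Pairwise Wald contrasts between groups are flagged
#' at \code{alpha / n_planned_tests} (Bonferroni over the planned tests;
#' the six planned tests of the study design give alpha/6).
#'
#' @param flags logical outcome per p-value.
#' @param article_ids cluster identifiers.
#' @param group_labels group label per flag (>= 2 groups, none empty).
#' @param n_planned_tests Bonferroni divisor (default 6).
#' @param alpha nominal level before correction (default 0.05).
#' @param nAGQ quadrature nodes (default 1; the likelihood-ratio test
#'   needs both fits under the same approximation).
#' @return list of class \code{"group_comparison"}: \code{test_statistic}
#'   (LR chi-squared), \code{df}, \code{p_value}, \code{alpha_corrected},
#'   \code{pairwise} (data.frame: pair, estimate (log-odds difference),
#'   p_value, significant).
#' @export
compare_groups <- function(flags, article_ids, group_labels,
                           n_planned_tests = 6, alpha = 0.05, nAGQ = 1) {
  flags <- as.logical(flags)
  if (!is.factor(group_labels)) group_labels <- factor(group_labels)
  stopifnot(length(flags) == length(article_ids),
            length(flags) == length(group_labels))
  if (nlevels(group_labels) < 2) {
    stop("need at least 2 groups to compare")
  }
  if (any(table(group_labels) == 0)) stop("empty group")
  dat <- data.frame(y = flags, article = factor(article_ids),
                    g = group_labels)
  fit1 <- lme4::glmer(y ~ g + (1 | article), data = dat,
                      family = stats::binomial(), nAGQ = nAGQ)
  fit0 <- lme4::glmer(y ~ 1 + (1 | article), data = dat,
                      family = stats::binomial(), nAGQ = nAGQ)
  an <- stats::anova(fit1, fit0)
  lr <- an$Chisq[2]
  df <- an$Df[2]
  p <- an$`Pr(>Chisq)`[2]

  # pairwise Wald contrasts on the fixed effects
  beta <- lme4::fixef(fit1)
  V <- as.matrix(stats::vcov(fit1))
  lev <- levels(dat$g)
  k <- length(lev)
  pairs <- utils::combn(k, 2)
  pw <- data.frame(pair = character(ncol(pairs)),
                   estimate = numeric(ncol(pairs)),
                   p_value = numeric(ncol(pairs)),
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b2 <- pairs[2, j]
    cvec <- numeric(length(beta))
    names(cvec) <- names(beta)
    # treatment coding: level 1 is the reference
    if (a > 1) cvec[paste0("g", lev[a])] <- -1
    if (b2 > 1) cvec[paste0("g", lev[b2])] <- 1
    estj <- sum(cvec * beta)
    sej <- sqrt(drop(t(cvec) %*% V %*% cvec))
    pw$pair[j] <- paste(lev[a], lev[b2], sep = " vs ")
    pw$estimate[j] <- estj
    pw$p_value[j] <- 2 * stats::pnorm(abs(estj / sej), lower.tail = FALSE)
  }
  alpha_c <- alpha / n_planned_tests
  pw$significant <- pw$p_value < alpha_c
  out <- list(test_statistic = lr, df = df, p_value = p,
              alpha_corrected = alpha_c, pairwise = pw,
              n = nrow(dat), fit = fit1)
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("LR test: chi2(%d, N = %d) = %.2f, p = %.4g (corrected alpha %.4g)\n",
              x$df, x$n, x$test_statistic, x$p_value, x$alpha_corrected))
  print(x$pairwise)
  invisible(x)
}

#' Conditional probability of a gross error given an error, across groups
#'
#' Restricts the data to results flagged as errors and compares the
#' proportion that are gross between groups with [compare_groups()].
#' Validates the containment invariant (every gross error is an error).
#'
#' @param error_flags,gross_flags logical vectors (gross implies error).
#' @param article_ids,group_labels,n_planned_tests,alpha,nAGQ passed on.
#' @return a \code{"group_comparison"}.
#' @export
conditional_gross_given_error <- function(error_flags, gross_flags,
                                          article_ids, group_labels,
                                          n_planned_tests = 6,
                                          alpha = 0.05, nAGQ = 1) {
  error_flags <- as.logical(error_flags)
  gross_flags <- as.logical(gross_flags)
  if (any(gross_flags & !error_flags)) {
    stop("invariant breach: gross error flagged on a consistent result")
  }
  keep <- error_flags
  if (!any(keep)) stop("no errors in corpus: conditional subset is empty")
  compare_groups(gross_flags[keep], article_ids[keep],
                 droplevels(factor(group_labels)[keep]),
                 n_planned_tests = n_planned_tests, alpha = alpha,
                 nAGQ = nAGQ)
}
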