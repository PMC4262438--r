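#' Recompute the p-value implied by a test statistic
#'
#' Given a test family, the printed statistic and its degrees of freedom,
#' returns the p-value under the usual null distribution:
#' \describe{
#'   \item{t}{two-tailed Student-t tail probability at \code{|stat|} with
#'     \code{df1} degrees of freedom,}
#'   \item{F}{upper tail of F(\code{df1}, \code{df2}) at \code{stat},}
#'   \item{chi2}{upper tail of chi-squared(\code{df1}) at \code{stat},}
#'   \item{Z}{two-tailed standard-normal tail at \code{|stat|},}
#'   \item{r}{the correlation is converted to
#'     \eqn{t = r\sqrt{df_1/(1-r^2)}} and treated as a two-tailed t with
#'     \code{df1} (= n - 2) degrees of freedom.}
#' }
#' t, r and Z are two-tailed by convention; F and chi-squared are inherently
#' one-tailed (upper). Negative t, r, Z are handled through the absolute
#' value; a negative F or chi-squared statistic is invalid and rejected.
#'
#' @param family one of \code{"t"}, \code{"F"}, \code{"chi2"}, \code{"r"},
#'   \code{"Z"}. Vectorised over all numeric arguments.
#' @param stat the printed test statistic.
#' @param df1 first (or only) degrees of freedom; may be fractional
#'   (corrected-df tests). Not used for Z.
#' @param df2 denominator degrees of freedom (F only).
#' @return p-value(s) in [0, 1]. \code{|r| = 1} returns 0 exactly.
#' @examples
#' computed_p("F", 0.54, 1, 20)   # ~ 0.47
#' computed_p("t", 0, 28)         # 1
#' @export
computed_p <- function(family, stat, df1 = NA_real_, df2 = NA_real_) {
  if (!(family %in% c("t", "F", "chi2", "r", "Z"))) {
    stop("unknown test family: ", family)
  }
  n <- max(length(stat), length(df1), length(df2))
  stat <- rep_len(as.numeric(stat), n)
  df1 <- rep_len(as.numeric(df1), n)
  df2 <- rep_len(as.numeric(df2), n)

  if (family != "Z" && any(is.na(df1) | df1 <= 0)) {
    stop("df1 must be positive for family '", family, "'")
  }
  switch(family,
    t = 2 * stats::pt(abs(stat), df1, lower.tail = FALSE),
    F = {
      if (any(is.na(df2) | df2 <= 0)) stop("df2 must be positive for F")
      if (any(stat < 0)) stop("negative F statistic is invalid")
      stats::pf(stat, df1, df2, lower.tail = FALSE)
    },
    chi2 = {
      if (any(stat < 0)) stop("negative chi-squared statistic is invalid")
      stats::pchisq(stat, df1, lower.tail = FALSE)
    },
    Z = 2 * stats::pnorm(abs(stat), lower.tail = FALSE),
    r = {
      if (any(abs(stat) > 1)) stop("|r| > 1 is invalid")
      r <- abs(stat)
      p <- ifelse(r == 1, 0,
        2 * stats::pt(r * sqrt(df1 / (1 - r^2)), df1, lower.tail = FALSE))
      p
    }
  )
}

#' Bounds on the recomputed p induced by rounding of the printed statistic
#'
#' A statistic printed with \code{d} decimals stands for any true value within
#' half a last-digit unit, \eqn{h = 0.5 \cdot 10^{-d}}, of the printed number.
#' Because p is monotone non-increasing in the statistic's magnitude for every
#' supported family, evaluating at the two endpoints of
#' \code{[|stat| - h, |stat| + h]} bounds the recomputed p:
#' \code{p_hi} at the smaller magnitude, \code{p_lo} at the larger, and
#' \code{p_mid} at the printed value itself. When the statistic was itself
#' reported as an inequality (\code{stat_comp} \code{"<"} or \code{">"}), the
#' corresponding bound is widened to the distribution's limit.
#'
#' @param family,stat,df1,df2 as in [computed_p()].
#' @param stat_dec number of decimal digits the statistic was printed with.
#' @param stat_comp comparator the statistic was reported with: \code{"eq"}
#'   (default), \code{"lt"} or \code{"gt"}.
#' @return a list of class \code{"p_interval"} with elements \code{p_lo},
#'   \code{p_mid}, \code{p_hi} (always \code{p_lo <= p_mid <= p_hi}).
#' @examples
#' p_interval("F", 0.54, 2, df1 = 1, df2 = 20)
#' @export
p_interval <- function(family, stat, stat_dec, df1 = NA_real_, df2 = NA_real_,
                       stat_comp = "eq") {
  stopifnot(stat_dec >= 0)
  h <- 0.5 * 10^(-stat_dec)
  a <- abs(stat)
  lo_stat <- max(a - h, 0)
  hi_stat <- a + h
  if (family == "r") hi_stat <- min(hi_stat, 1)

  p_mid <- computed_p(family, a, df1, df2)
  p_hi <- computed_p(family, lo_stat, df1, df2)
  p_lo <- computed_p(family, hi_stat, df1, df2)

  if (stat_comp == "lt") p_hi <- 1
  if (stat_comp == "gt") p_lo <- 0
  # guard against tiny floating asymmetries
  p_lo <- min(p_lo, p_mid)
  p_hi <- max(p_hi, p_mid)
  structure(list(p_lo = p_lo, p_mid = p_mid, p_hi = p_hi),
            class = "p_interval")
}

#' @export
print.p_interval <- function(x, ...) {
  cat(sprintf("recomputed p = %.6g  [%.6g, %.6g]\n", x$p_mid, x$p_lo, x$p_hi))
  invisible(x)
}

#' Rounding interval for a report row
#'
#' Convenience wrapper applying [p_interval()] to one row of the table
#' returned by [scan_text()].
#'
#' @param report a single-row data.frame with columns \code{family},
#'   \code{stat}, \code{stat_dec}, \code{stat_comp}, \code{df1}, \code{df2}.
#' @return a \code{"p_interval"} object.
#' @export
p_interval_from_report <- function(report) {
  stopifnot(nrow(report) == 1L)
  p_interval(report$family, report$stat, report$stat_dec,
             df1 = report$df1, df2 = report$df2,
             stat_comp = report$stat_comp)
}
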