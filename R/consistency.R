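# Rounding-aware comparison of reported and recomputed p-values ----------

#' Admissible region of true p-values implied by a reported p
#'
#' A p-value printed as \code{p = v} with \code{d} decimals stands for any
#' true p within half a last-digit unit of \code{v}:
#' \code{[v - 0.5e-d, v + 0.5e-d]}, intersected with [0, 1].
#' \code{p < v} is taken as the strict claim \code{[0, v)} and
#' \code{p > v} as \code{(v, 1]} (a one-sided claim carries no rounding
#' band). \code{ns} claims \code{(alpha, 1]}. The special print
#' \code{p = .000} (zero at \code{d} decimals) stands for \code{[0, 0.5e-d)}.
#'
#' @param p_comp \code{"eq"}, \code{"lt"}, \code{"gt"} or \code{"ns"}.
#' @param p reported p-value (NA for \code{ns}).
#' @param p_dec number of printed decimals.
#' @param alpha significance threshold used for \code{ns} (default 0.05).
#' @return list with \code{lo}, \code{hi}, \code{lo_open}, \code{hi_open}.
#' @examples
#' reported_p_region("eq", 0.03, 2)   # [0.025, 0.035]
#' reported_p_region("lt", 0.05, 2)   # [0, 0.05)
#' @export
reported_p_region <- function(p_comp, p, p_dec, alpha = 0.05) {
  if (p_comp != "ns") {
    if (is.na(p) || p < 0 || p > 1) stop("reported p must lie in [0, 1]")
  }
  switch(p_comp,
    eq = {
      h <- 0.5 * 10^(-p_dec)
      if (p == 0) {
        list(lo = 0, hi = h, lo_open = FALSE, hi_open = TRUE)
      } else {
        list(lo = max(p - h, 0), hi = min(p + h, 1),
             lo_open = FALSE, hi_open = FALSE)
      }
    },
    lt = list(lo = 0, hi = p, lo_open = FALSE, hi_open = TRUE),
    gt = list(lo = p, hi = 1, lo_open = TRUE, hi_open = FALSE),
    ns = list(lo = alpha, hi = 1, lo_open = TRUE, hi_open = FALSE),
    stop("unknown p comparator: ", p_comp)
  )
}

# closed interval [lo, hi] vs possibly half-open region
.overlaps <- function(p_lo, p_hi, region) {
  upper_ok <- if (region$hi_open) p_lo < region$hi else p_lo <= region$hi
  lower_ok <- if (region$lo_open) p_hi > region$lo else p_hi >= region$lo
  upper_ok && lower_ok
}

.near <- function(a, b, tol = 1e-12) !is.na(a) && abs(a - b) < tol

#' Classify one result as consistent, error, or gross error
#'
#' The result is consistent when the recomputed-p interval (statistic
#' rounding propagated, [p_interval()]) overlaps the admissible region of
#' the reported p ([reported_p_region()]). If inconsistent and the result
#' was described as one-tailed, a one-tailed rescue is attempted for the
#' symmetric families (t, r, Z): the interval is halved and the overlap
#' re-tested; success marks the result consistent with
#' \code{one_tailed_applied = TRUE}.
#'
#' An inconsistency is a gross error when it could have changed the
#' significance decision: the result is reported significant while the
#' recomputed p lies above \code{alpha}, or vice versa. Reported
#' significance is read from the comparator (\code{p < v} with
#' \code{v <= alpha} claims significance; \code{p > v} with
#' \code{v >= alpha}, or \code{ns}, claims nonsignificance; \code{p = v}
#' claims the side of \code{alpha} that \code{v} lies on, with \code{v}
#' exactly at \code{alpha} resolved by the sentence's significance wording
#' and left undetermined otherwise -- an undetermined claim can be an error
#' but never a gross error). Recomputed significance is judged by the whole
#' rounding interval: the gross flag is raised only when the entire
#' interval lies on the opposite side of \code{alpha}, so statistic
#' rounding never manufactures a decision error. For one-tailed results
#' the halved interval is folded in, making the rule conservative under
#' either reading of sidedness.
#'
#' @param report one row from [scan_text()].
#' @param interval the matching \code{"p_interval"} (default recomputed
#'   from the report).
#' @param alpha significance threshold (default 0.05).
#' @return a one-row data.frame: \code{consistent}, \code{error},
#'   \code{gross_error}, \code{one_tailed_applied}, \code{reason}.
#' @export
classify_report <- function(report, interval = p_interval_from_report(report),
                            alpha = 0.05) {
  stopifnot(nrow(report) == 1L, alpha > 0, alpha < 1)
  as.data.frame(.classify_one(report, interval, alpha),
                stringsAsFactors = FALSE)
}

# `report` may be a one-row data.frame or an equivalent named list
.classify_one <- function(report, interval, alpha) {
  region <- reported_p_region(report$p_comp, report$p, report$p_dec, alpha)

  consistent <- .overlaps(interval$p_lo, interval$p_hi, region)
  one_tailed_applied <- FALSE
  symmetric <- report$family %in% c("t", "r", "Z")
  if (!consistent && isTRUE(report$one_tailed) && symmetric) {
    if (.overlaps(interval$p_lo / 2, interval$p_hi / 2, region)) {
      consistent <- TRUE
      one_tailed_applied <- TRUE
    }
  }
  error <- !consistent

  # reported significance claim: TRUE / FALSE / NA (undetermined)
  pc <- report$p_comp
  pv <- report$p
  wording <- report$sig_wording
  rep_sig <- NA
  if (pc == "lt" && pv <= alpha) rep_sig <- TRUE
  else if (pc == "ns") rep_sig <- FALSE
  else if (pc == "gt" && pv >= alpha) rep_sig <- FALSE
  else if (pc == "eq") {
    if (.near(pv, alpha)) {
      if (identical(wording, "significant")) rep_sig <- TRUE
      else if (identical(wording, "nonsignificant")) rep_sig <- FALSE
    } else if (pv < alpha) rep_sig <- TRUE
    else rep_sig <- FALSE
  }

  lo_eval <- if (isTRUE(report$one_tailed) && symmetric)
    interval$p_lo / 2 else interval$p_lo
  hi_eval <- interval$p_hi
  gross <- error && !is.na(rep_sig) &&
    ((isTRUE(rep_sig) && lo_eval > alpha) ||
     (isFALSE(rep_sig) && hi_eval < alpha))

  reason <- if (consistent) {
    if (one_tailed_applied) "consistent_one_tailed" else "consistent"
  } else if (gross) {
    "gross_error"
  } else if (is.na(rep_sig)) {
    "error_indeterminate_significance"
  } else {
    "error_same_side"
  }

  list(consistent = consistent, error = error, gross_error = gross,
       one_tailed_applied = one_tailed_applied, reason = reason)
}

#' Classify a table of reports
#'
#' Validates every report ([validate_report()]), recomputes the rounding
#' interval for the valid ones and classifies each. Invalid reports are
#' excluded from the per-result table and returned in the
#' \code{"excluded"} attribute with their validation verdicts.
#'
#' @param reports a table from [scan_text()].
#' @param alpha significance threshold.
#' @return the reports table augmented with \code{computed_p}, \code{p_lo},
#'   \code{p_hi}, \code{consistent}, \code{error}, \code{gross_error},
#'   \code{one_tailed_applied}, \code{reason}; attribute \code{"excluded"}.
#' @export
classify_reports <- function(reports, alpha = 0.05) {
  nr <- nrow(reports)
  rows <- lapply(seq_len(nr), function(i) lapply(reports, `[[`, i))
  verdicts <- vapply(rows, .validate_fields, character(1))
  excluded <- reports[verdicts != "valid", , drop = FALSE]
  excluded$exclusion <- verdicts[verdicts != "valid"]
  keep <- which(verdicts == "valid")
  valid <- reports[keep, , drop = FALSE]

  nv <- length(keep)
  computed_p <- p_lo <- p_hi <- numeric(nv)
  consistent <- error <- gross_error <- one_tailed_applied <- logical(nv)
  reason <- character(nv)
  for (i in seq_len(nv)) {
    r <- rows[[keep[i]]]
    iv <- p_interval(r$family, r$stat, r$stat_dec,
                     df1 = r$df1, df2 = r$df2, stat_comp = r$stat_comp)
    cl <- .classify_one(r, iv, alpha)
    computed_p[i] <- iv$p_mid; p_lo[i] <- iv$p_lo; p_hi[i] <- iv$p_hi
    consistent[i] <- cl$consistent; error[i] <- cl$error
    gross_error[i] <- cl$gross_error
    one_tailed_applied[i] <- cl$one_tailed_applied
    reason[i] <- cl$reason
  }
  out <- cbind(valid,
               data.frame(computed_p = computed_p, p_lo = p_lo, p_hi = p_hi,
                          consistent = consistent, error = error,
                          gross_error = gross_error,
                          one_tailed_applied = one_tailed_applied,
                          reason = reason, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
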