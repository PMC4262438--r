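# APA result grammar -----------------------------------------------------
#
# One PCRE pattern per test family, joined into a single alternation. A
# result is matched only when the p-clause follows the statistic directly
# (", p < .05"); anything interleaved (effect sizes etc.) breaks the match,
# mirroring the known retrieval limitation of APA scanners. Those near
# misses are reported separately as skipped candidates.

.num <- "[0-9]+(?:\\.[0-9]+)?"
.pnum <- "(?:[0-9]+\\.[0-9]+|\\.[0-9]+|[0-9]+)"
.statnum <- "[-−]?(?:[0-9]+\\.[0-9]+|\\.[0-9]+|[0-9]+)"
.chisym <- "(?:χ²|χ2|[Cc]hi-square|[Cc]hi2)"

.stat_part <- paste0(
  "(?:Wald\\s+)?",
  "(?:",
  "\\b(t)\\s*\\(\\s*(", .num, ")\\s*\\)",
  "|\\b(F)\\s*\\(\\s*(", .num, ")\\s*,\\s*(", .num, ")\\s*\\)",
  "|\\b(r)\\s*\\(\\s*(", .num, ")\\s*\\)",
  "|(", .chisym, ")\\s*\\(\\s*(", .num, ")\\s*(?:,\\s*N\\s*=\\s*([0-9,]+)\\s*)?\\)",
  "|\\b(Z|z)\\b",
  ")",
  "\\s*(=|<|>)\\s*",
  "(", .statnum, ")"
)

.p_part <- paste0("\\s*,\\s*p\\s*(=|<|>)\\s*(ns|n\\.s\\.|", .pnum, ")")

.full_pattern <- paste0(.stat_part, .p_part)

.comp_map <- c("=" = "eq", "<" = "lt", ">" = "gt")

.decimals <- function(token) {
  ifelse(grepl(".", token, fixed = TRUE),
         nchar(sub("^[^.]*\\.", "", token)), 0L)
}

.capture_df <- function(text, pattern) {
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")
  list(start = as.integer(m), len = attr(m, "match.length"),
       cap = function(i, g) {
         if (cl[i, g] == 0L) NA_character_
         else substr(text, cs[i, g], cs[i, g] + cl[i, g] - 1L)
       },
       n = length(m))
}

.empty_reports <- function() {
  data.frame(article_id = character(), study_id = character(),
             family = character(), df1 = numeric(), df2 = numeric(),
             n = integer(), stat_comp = character(), stat = numeric(),
             stat_dec = integer(), p_comp = character(), p = numeric(),
             p_dec = integer(), one_tailed = logical(),
             sig_wording = character(), span_start = integer(),
             span_end = integer(), raw = character(), post = character(),
             stringsAsFactors = FALSE)
}

#' Extract APA-formatted test results from article text
#'
#' Scans plain text for statistical results reported in APA style --
#' \code{t(28) = 2.20, p = .036}, \code{F(1, 20) = 9.5, p < .006},
#' \code{chi2(1, N = 320) = 22.31, p < .001}, \code{r(30) = .52, p = .002},
#' \code{Z = 1.96, p = .05} -- and returns one row per result, in document
#' order. The grammar accepts \code{=}, \code{<}, \code{>} around both the
#' statistic and the p-value, p-values with or without a leading zero,
#' several spellings of the chi-squared symbol, a \code{Wald} prefix
#' (\code{Wald chi2(df)} parses as chi2, \code{Wald Z} as Z), decimal
#' degrees of freedom, and \code{ns} / \code{n.s.} in place of a numeric
#' p-value. Results where other quantities are printed between the test
#' statistic and the p-value are not matched (a documented limitation of
#' this reporting grammar); such near misses are returned in the
#' \code{"skipped"} attribute with their offsets.
#'
#' Context heuristics ([detect_sidedness()], [detect_sig_wording()]) are
#' applied to fill \code{one_tailed} and \code{sig_wording}.
#'
#' @param text document text (UTF-8 plain text; see [strip_html()]).
#' @param article_id non-empty identifier attached to every row.
#' @param study_id optional study identifier (caller-supplied).
#' @param window character distance used by [detect_sidedness()].
#' @return a data.frame with columns \code{article_id, study_id, family,
#'   df1, df2, n, stat_comp, stat, stat_dec, p_comp, p, p_dec, one_tailed,
#'   sig_wording, span_start, span_end, raw, post}; attribute
#'   \code{"skipped"} holds a data.frame of skipped candidates
#'   (\code{offset}, \code{raw}, \code{reason}).
#' @examples
#' scan_text("We found t(28) = 2.20, p = .036 overall.", "a1")
#' @export
scan_text <- function(text, article_id, study_id = NA_character_,
                      window = 200) {
  stopifnot(is.character(text), length(text) == 1L,
            nzchar(article_id))
  # normalise unicode minus so signs parse; same character width
  text <- gsub("−", "-", text)

  cap <- .capture_df(text, .full_pattern)
  skipped <- data.frame(offset = integer(), raw = character(),
                        reason = character(), stringsAsFactors = FALSE)
  if (is.null(cap)) {
    out <- .empty_reports()
    attr(out, "skipped") <- .skipped_candidates(text, integer(0))
    return(out)
  }

  nm <- cap$n
  family <- character(nm); df1 <- rep(NA_real_, nm); df2 <- rep(NA_real_, nm)
  nn <- rep(NA_integer_, nm); stat_comp <- character(nm)
  stat <- numeric(nm); stat_dec <- integer(nm)
  p_comp <- character(nm); p <- rep(NA_real_, nm); p_dec <- rep(NA_integer_, nm)
  for (i in seq_len(nm)) {
    g <- function(j) cap$cap(i, j)
    # capture layout: 1 t, 2 t-df | 3 F, 4 df1, 5 df2 | 6 r, 7 r-df |
    # 8 chi-sym, 9 chi-df, 10 N | 11 Z | 12 stat comp, 13 stat |
    # 14 p comp, 15 p token
    if (!is.na(g(1))) {
      family[i] <- "t"; df1[i] <- as.numeric(g(2))
    } else if (!is.na(g(3))) {
      family[i] <- "F"; df1[i] <- as.numeric(g(4)); df2[i] <- as.numeric(g(5))
    } else if (!is.na(g(6))) {
      family[i] <- "r"; df1[i] <- as.numeric(g(7))
    } else if (!is.na(g(8))) {
      family[i] <- "chi2"; df1[i] <- as.numeric(g(9))
      if (!is.na(g(10))) nn[i] <- as.integer(gsub(",", "", g(10)))
    } else {
      family[i] <- "Z"
    }
    stat_tok <- g(13)
    p_tok <- g(15)
    is_ns <- p_tok %in% c("ns", "n.s.")
    stat_comp[i] <- .comp_map[[g(12)]]
    stat[i] <- as.numeric(stat_tok)
    stat_dec[i] <- .decimals(stat_tok)
    p_comp[i] <- if (is_ns) "ns" else .comp_map[[g(14)]]
    if (!is_ns) {
      p[i] <- as.numeric(p_tok)
      p_dec[i] <- .decimals(p_tok)
    }
  }
  span_start <- cap$start
  span_end <- cap$start + cap$len - 1L
  out <- data.frame(
    article_id = article_id, study_id = study_id, family = family,
    df1 = df1, df2 = df2, n = nn, stat_comp = stat_comp, stat = stat,
    stat_dec = stat_dec, p_comp = p_comp, p = p, p_dec = p_dec,
    one_tailed = NA, sig_wording = NA_character_,
    span_start = span_start, span_end = span_end,
    raw = substring(text, span_start, span_end),
    post = substring(text, span_end + 1L,
                     pmin(nchar(text), span_end + 15L)),
    stringsAsFactors = FALSE)

  out$one_tailed <- vapply(seq_len(nrow(out)), function(i) {
    detect_sidedness(text, out$span_start[i], out$span_end[i], window)
  }, logical(1))
  out$sig_wording <- vapply(seq_len(nrow(out)), function(i) {
    detect_sig_wording(text, out$span_start[i], out$span_end[i])
  }, character(1))

  attr(out, "skipped") <- .skipped_candidates(text, cap$start)
  out
}

# Candidates that start like a result but whose p-clause is not adjacent
# (e.g. "F(1, 46) = 8.41, eta2 = .16, p = .006"): counted, never parsed.
.skipped_candidates <- function(text, matched_starts) {
  cap <- .capture_df(text, .stat_part)
  if (is.null(cap)) {
    return(data.frame(offset = integer(), raw = character(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  keep <- !(cap$start %in% matched_starts)
  offs <- cap$start[keep]
  lens <- cap$len[keep]
  if (!length(offs)) {
    return(data.frame(offset = integer(), raw = character(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  # only flag those with a p-clause nearby: interleaved-token situation
  near_p <- vapply(seq_along(offs), function(i) {
    tail_txt <- substr(text, offs[i] + lens[i], offs[i] + lens[i] + 80L)
    grepl("\\bp\\s*[=<>]", tail_txt, perl = TRUE)
  }, logical(1))
  data.frame(offset = offs[near_p],
             raw = substr(text, offs[near_p], offs[near_p] + lens[near_p] - 1L),
             reason = "tokens_between_statistic_and_p",
             stringsAsFactors = FALSE)
}

#' Detect one-tailed wording near a result
#'
#' Returns \code{TRUE} when one of the keywords \code{"one-tailed"},
#' \code{"one-sided"} or \code{"directional"} (case-insensitive; space or
#' hyphen) occurs within \code{window} characters of the result's span.
#' Distance is measured from the nearest edge of the span to the nearest
#' character of the keyword; a keyword exactly \code{window + 1} characters
#' away does not count.
#'
#' @param text document text.
#' @param span_start,span_end character offsets of the result in \code{text}.
#' @param window maximum distance in characters (default 200).
#' @export
detect_sidedness <- function(text, span_start, span_end, window = 200) {
  kw <- gregexpr("(?i)one[- ]tailed|one[- ]sided|directional", text,
                 perl = TRUE)[[1]]
  if (kw[1] == -1L) return(FALSE)
  ks <- as.integer(kw)
  ke <- ks + attr(kw, "match.length") - 1L
  dist <- ifelse(ke < span_start, span_start - ke,
          ifelse(ks > span_end, ks - span_end, 0L))
  any(dist <= window)
}

#' Detect significance wording in the sentence containing a result
#'
#' The sentence is the span between terminal punctuation marks
#' (\code{.}, \code{!}, \code{?} followed by whitespace). Returns
#' \code{"nonsignificant"} when a negation-qualified significance phrase
#' ("not significant", "non-significant", "nonsignificant", "no
#' significant") occurs, \code{"significant"} when
#' "significant"/"significantly" occurs un-negated, else \code{"unknown"}.
#' Used to resolve results printed as \code{p = .05}, whose claimed
#' significance cannot be read off the number alone.
#'
#' @inheritParams detect_sidedness
#' @export
detect_sig_wording <- function(text, span_start, span_end) {
  bnd <- gregexpr("[.!?](?=\\s)", text, perl = TRUE)[[1]]
  bounds <- if (bnd[1] == -1L) integer(0) else as.integer(bnd)
  lo <- c(0L, bounds)          # sentence starts just after a boundary
  s_start <- max(lo[lo < span_start]) + 1L
  hi <- c(bounds, nchar(text))
  s_end <- min(hi[hi >= span_end])
  sentence <- substr(text, s_start, s_end)

  neg <- "(?i)\\b(?:not\\s+(?:statistically\\s+)?significant|non-?\\s?significant|no\\s+significant)"
  if (grepl(neg, sentence, perl = TRUE)) return("nonsignificant")
  if (grepl("(?i)significant", sentence, perl = TRUE)) return("significant")
  "unknown"
}

#' Validate an extracted report before checking
#'
#' Mirrors the exclusions applied before consistency checking: p-values
#' reported as larger than 1 are excluded (\code{"invalid_p_above_one"}),
#' p-values followed by power-of-ten notation ("x 10", "e-5") cannot be
#' read at their printed precision (\code{"unsupported_notation"}), and a
#' statistic outside its distribution's support (negative F or chi-squared,
#' |r| > 1) is \code{"invalid_statistic"}. Only \code{"valid"} reports
#' proceed to recomputation.
#'
#' @param report one row of the table returned by [scan_text()].
#' @return one of \code{"valid"}, \code{"invalid_p_above_one"},
#'   \code{"unsupported_notation"}, \code{"invalid_statistic"}.
#' @export
validate_report <- function(report) {
  stopifnot(nrow(report) == 1L)
  .validate_fields(report)
}

# `report` may be a one-row data.frame or an equivalent named list
.validate_fields <- function(report) {
  post <- if (is.null(report$post)) "" else report$post
  if (grepl("^\\s*(?:[×xX]\\s*10|[eE][-+]?[0-9])", post, perl = TRUE)) {
    return("unsupported_notation")
  }
  if (!is.na(report$p) && report$p > 1) return("invalid_p_above_one")
  if (report$family %in% c("F", "chi2") && report$stat < 0) {
    return("invalid_statistic")
  }
  if (report$family == "r" && abs(report$stat) > 1) {
    return("invalid_statistic")
  }
  "valid"
}

#' Strip HTML to plain text
#'
#' Convenience wrapper around xml2 for articles supplied as HTML: parses
#' the document and returns its text content with tags removed.
#'
#' @param html a length-one character vector of HTML.
#' @return plain text.
#' @export
strip_html <- function(html) {
  xml2::xml_text(xml2::read_html(html))
}
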