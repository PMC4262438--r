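# Corpus-level driving: files -> per-result and per-article tables -------

#' Check a single document
#'
#' Runs the full pipeline on in-memory text: extraction, context
#' heuristics, validation, recomputation and classification.
#'
#' @param text document text (plain text; pass HTML through [strip_html()]
#'   first, or use [check_corpus()] which does so by extension).
#' @param article_id identifier for the document.
#' @param alpha significance threshold (default 0.05).
#' @param window sidedness search window in characters (default 200).
#' @param study_id optional study identifier attached to every result.
#' @return list with \code{results} (classified per-result table),
#'   \code{skipped} (near-miss candidates) and \code{excluded}
#'   (reports removed at validation).
#' @export
check_text <- function(text, article_id, alpha = 0.05, window = 200,
                       study_id = NA_character_) {
  reports <- scan_text(text, article_id, study_id = study_id,
                       window = window)
  skipped <- attr(reports, "skipped")
  if (nrow(skipped)) skipped$article_id <- article_id
  results <- classify_reports(reports, alpha = alpha)
  excluded <- attr(results, "excluded")
  attr(results, "excluded") <- NULL
  list(results = results, skipped = skipped, excluded = excluded)
}

.read_article <- function(path) {
  if (!file.exists(path)) stop("cannot open file '", path, "'")
  txt <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
               collapse = "\n")
  if (grepl("\\.(html?|xml)$", path, ignore.case = TRUE)) {
    txt <- strip_html(txt)
  }
  txt
}

#' Check a corpus of article files
#'
#' Reads each file (plain text, or HTML stripped to text), runs
#' [check_text()], joins optional per-article metadata and aggregates
#' per-article summaries. Unreadable files are recorded and the run
#' continues; duplicate \code{article_id}s in the metadata are a hard
#' error.
#'
#' @param paths character vector of file paths.
#' @param metadata optional data.frame keyed by \code{article_id}; a
#'   \code{journal} column, if present, is joined onto both tables.
#' @param alpha,window as in [check_text()].
#' @param first_study_only if \code{TRUE}, restrict the per-article
#'   summaries to results whose \code{study_id} equals the first
#'   (minimum) study id seen in that article; requires caller-supplied
#'   study ids (automatic study segmentation is out of scope).
#' @return list with \code{results}, \code{articles}
#'   (per-article summary), \code{skipped}, \code{excluded} and
#'   \code{file_errors}.
#' @export
check_corpus <- function(paths, metadata = NULL, alpha = 0.05, window = 200,
                         first_study_only = FALSE) {
  if (!is.null(metadata)) {
    if (anyDuplicated(metadata$article_id)) {
      stop("duplicate article_id in metadata")
    }
  }
  results <- list(); skipped <- list(); excluded <- list()
  file_errors <- data.frame(path = character(), message = character(),
                            stringsAsFactors = FALSE)
  for (path in paths) {
    id <- tools::file_path_sans_ext(basename(path))
    chk <- tryCatch({
      check_text(.read_article(path), id, alpha = alpha, window = window)
    }, error = function(e) e)
    if (inherits(chk, "error")) {
      file_errors <- rbind(file_errors,
                           data.frame(path = path,
                                      message = conditionMessage(chk),
                                      stringsAsFactors = FALSE))
      next
    }
    results[[id]] <- chk$results
    skipped[[id]] <- chk$skipped
    excluded[[id]] <- chk$excluded
  }
  results <- if (length(results)) do.call(rbind, c(results, make.row.names = FALSE))
    else cbind(.empty_reports(),
               data.frame(computed_p = numeric(0), p_lo = numeric(0),
                          p_hi = numeric(0), consistent = logical(0),
                          error = logical(0), gross_error = logical(0),
                          one_tailed_applied = logical(0),
                          reason = character(0)))
  skipped <- if (length(skipped)) do.call(rbind, c(skipped, make.row.names = FALSE))
    else data.frame()
  excluded <- if (length(excluded)) do.call(rbind, c(excluded, make.row.names = FALSE))
    else data.frame()

  if (!is.null(metadata) && "journal" %in% names(metadata) && nrow(results)) {
    results$journal <- metadata$journal[match(results$article_id,
                                              metadata$article_id)]
  }
  articles <- summarize_articles(results, metadata = metadata,
                                 first_study_only = first_study_only)
  list(results = results, articles = articles, skipped = skipped,
       excluded = excluded, file_errors = file_errors)
}

#' Aggregate per-result classifications to per-article summaries
#'
#' @param results a classified per-result table.
#' @param metadata optional metadata with \code{article_id} and
#'   \code{journal}.
#' @param first_study_only restrict to each article's first study
#'   (requires non-missing \code{study_id}).
#' @return data.frame with one row per article: \code{article_id},
#'   \code{journal}, \code{n_reports}, \code{n_errors}, \code{n_gross},
#'   \code{any_error}, \code{any_gross}, \code{first_study_only}.
#' @export
summarize_articles <- function(results, metadata = NULL,
                               first_study_only = FALSE) {
  if (first_study_only && nrow(results)) {
    keep <- rep(FALSE, nrow(results))
    for (id in unique(results$article_id)) {
      rows <- which(results$article_id == id)
      sid <- results$study_id[rows]
      if (all(is.na(sid))) { keep[rows] <- TRUE; next }
      keep[rows] <- !is.na(sid) & sid == min(sid, na.rm = TRUE)
    }
    results <- results[keep, , drop = FALSE]
  }
  ids <- unique(results$article_id)
  out <- data.frame(
    article_id = ids,
    journal = rep(NA_character_, length(ids)),
    n_reports = vapply(ids, function(i) sum(results$article_id == i), integer(1)),
    n_errors = vapply(ids, function(i)
      sum(results$error[results$article_id == i]), integer(1)),
    n_gross = vapply(ids, function(i)
      sum(results$gross_error[results$article_id == i]), integer(1)),
    stringsAsFactors = FALSE)
  out$any_error <- out$n_errors > 0L
  out$any_gross <- out$n_gross > 0L
  out$first_study_only <- rep(first_study_only, length(ids))
  if (!is.null(metadata) && "journal" %in% names(metadata)) {
    out$journal <- metadata$journal[match(out$article_id, metadata$article_id)]
  } else if ("journal" %in% names(results)) {
    out$journal <- results$journal[match(out$article_id, results$article_id)]
  }
  rownames(out) <- NULL
  out
}

#' Binary co-piloting coding
#'
#' Codes an involvement count as co-piloted (1) when two or more persons
#' were involved in a task, 0 when exactly one person was.
#'
#' @param involvement_count integer vector of counts, each >= 1.
#' @return integer vector of 0/1.
#' @examples
#' code_copiloting(c(1, 2, 7))  # 0 1 1
#' @export
code_copiloting <- function(involvement_count) {
  involvement_count <- as.integer(involvement_count)
  if (any(is.na(involvement_count)) || any(involvement_count < 1L)) {
    stop("involvement counts must be integers >= 1")
  }
  as.integer(involvement_count >= 2L)
}

#' Write a per-result table to CSV with the canonical column set
#'
#' @param results classified per-result table.
#' @param path output file.
#' @export
write_results_csv <- function(results, path) {
  cols <- c("article_id", "study_id", "family", "df1", "df2", "n",
            "stat_comp", "stat", "stat_dec", "p_comp", "p", "p_dec",
            "one_tailed", "sig_wording", "span_start", "span_end", "raw",
            "computed_p", "p_lo", "p_hi", "consistent", "error",
            "gross_error", "one_tailed_applied", "reason")
  cols <- intersect(cols, names(results))
  utils::write.csv(results[, cols, drop = FALSE], path, row.names = FALSE)
}
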