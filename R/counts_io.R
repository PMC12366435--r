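#' Construct a speaker-by-tag count table
#'
#' The in-memory form of the pipeline's input: one row per speaker with
#' a diagnostic group label, the total number of words/morphemes the
#' speaker produced, and a non-negative integer count for every tag of a
#' scheme.
#'
#' @param speaker_id Character vector of unique speaker identifiers.
#' @param group Character vector of group labels, values drawn from
#'   `groups`.
#' @param word_count Integer vector of per-speaker word totals (all
#'   >= 1).
#' @param counts Integer matrix, one row per speaker and one column per
#'   tag in scheme order.
#' @param scheme The [tag_scheme] the columns refer to.
#' @param groups Length-2 character vector declaring the label
#'   vocabulary; the first element is the positive (detection-target)
#'   class.
#' @return An object of class `speaker_counts`.
#' @export
speaker_counts <- function(speaker_id, group, word_count, counts, scheme,
                           groups = c("ASD", "non-ASD")) {
  stopifnot(inherits(scheme, "tag_scheme"))
  speaker_id <- as.character(speaker_id)
  group <- as.character(group)
  n <- length(speaker_id)
  if (n == 0L) stop("at least one speaker is required")
  if (anyDuplicated(speaker_id))
    stop("duplicate speaker_id: ",
         paste(unique(speaker_id[duplicated(speaker_id)]), collapse = ", "))
  if (length(groups) != 2L || anyDuplicated(groups))
    stop("'groups' must name two distinct labels")
  if (length(group) != n || !all(group %in% groups))
    stop("group labels must be one of: ", paste(groups, collapse = ", "))
  word_count <- as.integer(word_count)
  if (length(word_count) != n || anyNA(word_count) || any(word_count < 1L))
    stop("word_count must be a positive integer for every speaker")
  counts <- as.matrix(counts)
  if (nrow(counts) != n || ncol(counts) != length(scheme$tags))
    stop("counts must be ", n, " x ", length(scheme$tags))
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(speaker_id, scheme$tags)
  structure(list(speaker_id = speaker_id, group = group,
                 word_count = word_count, counts = counts,
                 scheme = scheme, groups = groups),
            class = "speaker_counts")
}

#' @export
print.speaker_counts <- function(x, ...) {
  cat("Speaker-by-tag counts: ", length(x$speaker_id), " speakers x ",
      ncol(x$counts), " tags\n", sep = "")
  tb <- table(factor(x$group, levels = x$groups))
  cat("  groups: ", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
      " (positive class: ", x$groups[1], ")\n", sep = "")
  invisible(x)
}

#' Read a tab-separated speaker-by-tag count table
#'
#' The file must be UTF-8 tab-separated with a header row of exactly
#' `speaker_id`, `group`, `word_count` followed by one column per tag of
#' `scheme`, in any order but with no tags missing and none unknown.
#'
#' @param path Path to the TSV file.
#' @param scheme The [tag_scheme] the columns must match.
#' @param groups Declared group-label vocabulary (positive class first).
#' @return A [speaker_counts] object with columns realigned to scheme
#'   order.
#' @export
read_counts_table <- function(path, scheme, groups = c("ASD", "non-ASD")) {
  stopifnot(inherits(scheme, "tag_scheme"))
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", fileEncoding = "UTF-8")
  hdr <- names(raw)
  fixed <- c("speaker_id", "group", "word_count")
  if (length(hdr) < 3L || !identical(hdr[1:3], fixed))
    stop("header must start with columns: ", paste(fixed, collapse = ", "))
  tag_cols <- hdr[-(1:3)]
  missing_tags <- setdiff(scheme$tags, tag_cols)
  if (length(missing_tags))
    stop("missing tag column(s): ", paste(missing_tags, collapse = ", "))
  unknown <- setdiff(tag_cols, scheme$tags)
  if (length(unknown))
    stop("unknown tag column(s): ", paste(unknown, collapse = ", "))
  if (nrow(raw) == 0L) stop("no data rows in ", path)

  parse_int <- function(values, column, min = 0L) {
    ok <- grepl("^[0-9]+$", values)
    if (!all(ok))
      stop(sprintf("malformed numeric value in row %d, column '%s': '%s'",
                   which(!ok)[1], column, values[which(!ok)[1]]))
    out <- as.integer(values)
    if (any(out < min))
      stop(sprintf("value below %d in row %d, column '%s'",
                   min, which(out < min)[1], column))
    out
  }
  word_count <- parse_int(raw$word_count, "word_count", min = 1L)
  counts <- vapply(scheme$tags,
                   function(tg) parse_int(raw[[tg]], tg, min = 0L),
                   integer(nrow(raw)))
  if (nrow(raw) == 1L) counts <- matrix(counts, nrow = 1L)
  speaker_counts(raw$speaker_id, raw$group, word_count, counts,
                 scheme, groups = groups)
}

#' Write a speaker-by-tag count table as TSV
#'
#' Inverse of [read_counts_table()]: emits the header
#' `speaker_id`, `group`, `word_count` followed by the scheme's tags in
#' order, then one row per speaker.
#'
#' @param records A [speaker_counts] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(records, path) {
  stopifnot(inherits(records, "speaker_counts"))
  df <- data.frame(speaker_id = records$speaker_id,
                   group = records$group,
                   word_count = records$word_count,
                   records$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Normalize tag counts to per-word frequencies
#'
#' Converts a count table into the Tag Linear Model's feature matrix by
#' dividing each speaker's tag counts by the total number of words that
#' speaker produced: `x[i, j] = c[i, j] / w[i]`.  This removes
#' differences in sheer speech quantity so that the model sees
#' proportional use of each linguistic resource.
#'
#' @param records A [speaker_counts] object (or a list of them sharing
#'   one scheme, which are row-bound).
#' @param positive Group label treated as the positive class (`y = 1`);
#'   defaults to the first element of the records' group vocabulary.
#' @return An object of class `feature_matrix`: list with the n-by-m
#'   numeric matrix `x`, binary vector `y`, `tag_names`, `speaker_ids`
#'   and `positive_class`.
#' @export
normalize_features <- function(records, positive = NULL) {
  if (is.list(records) && !inherits(records, "speaker_counts")) {
    if (length(records) == 0L) stop("empty record list")
    if (!all(vapply(records, inherits, logical(1), "speaker_counts")))
      stop("all elements must be speaker_counts objects")
    schemes <- lapply(records, function(r) r$scheme$tags)
    if (!all(vapply(schemes, identical, logical(1), schemes[[1]])))
      stop("records do not share a single tag scheme")
    records <- Reduce(function(a, b) {
      speaker_counts(c(a$speaker_id, b$speaker_id), c(a$group, b$group),
                     c(a$word_count, b$word_count),
                     rbind(a$counts, b$counts), a$scheme, a$groups)
    }, records)
  }
  stopifnot(inherits(records, "speaker_counts"))
  if (is.null(positive)) positive <- records$groups[1]
  if (!positive %in% records$groups)
    stop("'positive' must be one of: ",
         paste(records$groups, collapse = ", "))
  x <- records$counts / records$word_count
  y <- as.integer(records$group == positive)
  feature_matrix(x, y, tag_names = records$scheme$tags,
                 speaker_ids = records$speaker_id,
                 positive_class = positive)
}

#' Construct a feature matrix directly
#'
#' @param x Numeric n-by-m matrix of non-negative normalized
#'   frequencies.
#' @param y Binary (0/1) label vector of length n.
#' @param tag_names Column names (length m).
#' @param speaker_ids Row names (length n).
#' @param positive_class Label of the positive class (metadata only).
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(x, y, tag_names = colnames(x),
                           speaker_ids = rownames(x),
                           positive_class = "positive") {
  x <- as.matrix(x)
  if (is.null(tag_names)) tag_names <- sprintf("tag%03d", seq_len(ncol(x)))
  if (is.null(speaker_ids)) speaker_ids <- sprintf("s%03d", seq_len(nrow(x)))
  if (anyNA(x) || any(x < 0)) stop("x must be non-negative and complete")
  y <- as.integer(y)
  if (length(y) != nrow(x) || !all(y %in% c(0L, 1L)))
    stop("y must be a 0/1 vector with one entry per row of x")
  if (length(tag_names) != ncol(x) || length(speaker_ids) != nrow(x))
    stop("dimension names do not match x")
  dimnames(x) <- list(speaker_ids, tag_names)
  structure(list(x = x, y = y, tag_names = tag_names,
                 speaker_ids = speaker_ids,
                 positive_class = positive_class),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix: ", nrow(x$x), " speakers x ", ncol(x$x),
      " tags (positive class: ", x$positive_class, ", n+ = ", sum(x$y),
      ")\n", sep = "")
  invisible(x)
}

#' Write a bootstrap results table as CSV
#'
#' Emits the published table layout: columns `lexicogrammar`, `mean`,
#' `SD`, `p_value`, `significant`, with the three numeric columns
#' printed to 4 decimal places and rows in scheme (input) order.
#' Lines starting with `#` carry optional provenance metadata and are
#' skipped by [read_results_table()].
#'
#' @param result A [bootstrap_coefficients()] result, or any data frame
#'   with columns `tag`, `mean`, `sd`, `p_value`, `significant`.
#' @param path Output file path.
#' @param comments Optional character vector of provenance lines to
#'   embed (each written as `# <line>`).
#' @return `path`, invisibly.
#' @export
write_results_table <- function(result, path, comments = NULL) {
  df <- as.data.frame(result)
  need <- c("tag", "mean", "sd", "p_value", "significant")
  if (!all(need %in% names(df)))
    stop("result must have columns: ", paste(need, collapse = ", "))
  if (!all(is.finite(df$mean)) || !all(is.finite(df$sd)))
    stop("result contains non-finite moments")
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot open '", path,
                                           "' for writing: ",
                                           conditionMessage(e)))
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  writeLines("lexicogrammar,mean,SD,p_value,significant", con)
  writeLines(sprintf("\"%s\",%.4f,%.4f,%.4f,%s",
                     gsub("\"", "\"\"", df$tag), df$mean, df$sd,
                     df$p_value, ifelse(df$significant, "true", "false")),
             con)
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#'
#' @param path CSV file path.
#' @return Data frame with columns `tag`, `mean`, `sd`, `p_value`,
#'   `significant`.
#' @export
read_results_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("lexicogrammar", "mean", "SD", "p_value", "significant")
  if (!all(need %in% names(df)))
    stop("not a results table: expected columns ",
         paste(need, collapse = ", "))
  data.frame(tag = df$lexicogrammar, mean = df$mean, sd = df$SD,
             p_value = df$p_value,
             significant = df$significant %in% c("true", "TRUE", TRUE),
             stringsAsFactors = FALSE)
}
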