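#' Cognitive-functional domains recognized by the packaged mapping
#'
#' The seven domains used to interpret clause/phrase-level discriminators.
#' Their order fixes the order of every domain report.
#'
#' @return Character vector of the seven domain names.
#' @export
cognitive_domains <- function() {
  c("working memory",
    "inferential ability",
    "mental space construction",
    "joint attention",
    "weak central coherence",
    "self/other differentiation and agency",
    "restricted and repetitive behaviors")
}

#' Structural levels recognized by a tag scheme
#' @return Character vector of admissible `level` values.
#' @export
structural_levels <- function() {
  c("clause_phrase", "word", "particle", "filler", "other")
}

#' Construct a tag scheme
#'
#' A tag scheme is the annotation inventory behind a speaker-by-tag count
#' table: an ordered set of unique tag identifiers, each assigned to one
#' of at most 15 major categories, optionally annotated with the
#' structural level at which it varies and with the cognitive-functional
#' domains it is taken to reflect.
#'
#' @param tags Character vector of unique, non-empty tag identifiers.
#'   Their order fixes the column order of every downstream matrix.
#' @param categories Character vector, one category name per tag.  At
#'   most 15 distinct categories are allowed.
#' @param levels Optional character vector, one structural level per tag,
#'   each either `NA` (unannotated) or one of [structural_levels()].
#' @param domains Optional named list mapping a subset of tag
#'   identifiers to character vectors of domain names from
#'   [cognitive_domains()].
#' @return An object of class `tag_scheme`: a list with elements `tags`,
#'   `category` (named by tag), `level` (named by tag, possibly `NA`) and
#'   `domains` (named list).
#' @export
#' @examples
#' sc <- tag_scheme(c("A", "B"), c("cat1", "cat1"),
#'                  domains = list(A = "joint attention"))
tag_scheme <- function(tags, categories, levels = NULL, domains = list()) {
  if (!is.character(tags) || length(tags) == 0L)
    stop("'tags' must be a non-empty character vector")
  if (anyNA(tags) || any(!nzchar(tags)))
    stop("tag identifiers must be non-missing and non-empty")
  if (anyDuplicated(tags))
    stop("duplicate tag identifiers: ",
         paste(unique(tags[duplicated(tags)]), collapse = ", "))
  if (length(categories) != length(tags))
    stop("'categories' must have one entry per tag")
  if (anyNA(categories) || any(!nzchar(categories)))
    stop("every tag must have a category")
  if (length(unique(categories)) > 15L)
    stop("a tag scheme may use at most 15 categories; got ",
         length(unique(categories)))
  if (is.null(levels)) levels <- rep(NA_character_, length(tags))
  if (length(levels) != length(tags))
    stop("'levels' must have one entry per tag")
  bad <- !is.na(levels) & !(levels %in% structural_levels())
  if (any(bad))
    stop("unknown structural level(s): ",
         paste(unique(levels[bad]), collapse = ", "))
  if (!is.list(domains))
    stop("'domains' must be a named list")
  if (length(domains)) {
    if (is.null(names(domains)) || any(!nzchar(names(domains))))
      stop("'domains' must be named by tag identifier")
    unknown <- setdiff(names(domains), tags)
    if (length(unknown))
      stop("'domains' names not in 'tags': ",
           paste(unknown, collapse = ", "))
    for (tg in names(domains)) {
      d <- domains[[tg]]
      bad_d <- setdiff(d, cognitive_domains())
      if (length(bad_d))
        stop("unknown domain(s) for tag '", tg, "': ",
             paste(bad_d, collapse = ", "))
    }
  }
  structure(
    list(tags = tags,
         category = stats::setNames(as.character(categories), tags),
         level = stats::setNames(as.character(levels), tags),
         domains = domains[intersect(tags, names(domains))]),
    class = "tag_scheme")
}

#' @export
print.tag_scheme <- function(x, ...) {
  cat("Tag scheme: ", length(x$tags), " tags in ",
      length(unique(x$category)), " categories\n", sep = "")
  cat("  clause/phrase-level tags: ",
      sum(x$level == "clause_phrase", na.rm = TRUE), "\n", sep = "")
  cat("  domain-mapped tags: ", length(x$domains), "\n", sep = "")
  invisible(x)
}

#' The packaged default tag scheme
#'
#' Builds the default annotation inventory: the 46 published
#' discriminator items verbatim (with their category, structural level
#' and cognitive-domain annotations from [table1_discriminators()]),
#' padded with neutral placeholder tags to reach the configured total.
#' The full inventory behind the source corpus is not published, so the
#' placeholders stand in for the analyzed-but-nonsignificant items; they
#' carry no level or domain annotation.  Placeholders are spread over
#' four extra categories named after the systemic-functional networks
#' (MOOD, APPRAISAL, TRANSITIVITY, LOGICAL), bringing the category count
#' to 15.
#'
#' @param n_tags Total number of tags (default 135, the number of items
#'   analyzed; must be at least 46).
#' @return A [tag_scheme] with `n_tags` tags.
#' @export
#' @examples
#' sc <- default_tag_scheme()
#' length(sc$tags)
default_tag_scheme <- function(n_tags = 135L) {
  n_tags <- as.integer(n_tags)
  t1 <- table1_discriminators()
  if (is.na(n_tags) || n_tags < nrow(t1))
    stop("'n_tags' must be at least ", nrow(t1))
  n_extra <- n_tags - nrow(t1)
  extra_cat <- character(0)
  extra_tags <- character(0)
  if (n_extra > 0L) {
    nets <- c("MOOD (other)", "APPRAISAL (other)",
              "TRANSITIVITY (other)", "LOGICAL (other)")
    extra_cat <- nets[((seq_len(n_extra) - 1L) %% length(nets)) + 1L]
    extra_tags <- sprintf("%s/item-%03d", sub(" \\(other\\)", "", extra_cat),
                          seq_len(n_extra))
  }
  domains <- t1$domains
  names(domains) <- t1$tag
  domains <- domains[lengths(domains) > 0L]
  tag_scheme(
    tags = c(t1$tag, extra_tags),
    categories = c(t1$category, extra_cat),
    levels = c(t1$level, rep(NA_character_, n_extra)),
    domains = domains)
}

#' Read or write a tag scheme as JSON
#'
#' The interchange format is a single JSON object
#' `{"tags": [{"id", "category", "level", "domains"}, ...]}` where
#' `level` may be null and `domains` an empty array.
#'
#' @param path File path.
#' @return `read_tag_scheme()` returns a [tag_scheme];
#'   `write_tag_scheme()` returns `path` invisibly.
#' @export
read_tag_scheme <- function(path) {
  obj <- jsonlite::read_json(path)
  if (is.null(obj$tags))
    stop("scheme JSON must contain a 'tags' array")
  entries <- obj$tags
  ids <- vapply(entries, function(e) as.character(e$id %||% NA_character_),
                character(1))
  cats <- vapply(entries, function(e) as.character(e$category %||% NA_character_),
                 character(1))
  levs <- vapply(entries, function(e) {
    if (is.null(e$level)) NA_character_ else as.character(e$level)
  }, character(1))
  doms <- lapply(entries, function(e) unlist(e$domains) %||% character(0))
  names(doms) <- ids
  doms <- doms[lengths(doms) > 0L]
  tag_scheme(ids, cats, levs, doms)
}

#' @rdname read_tag_scheme
#' @param scheme A [tag_scheme].
#' @export
write_tag_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "tag_scheme"))
  entries <- lapply(scheme$tags, function(tg) {
    lev <- scheme$level[[tg]]
    list(id = tg,
         category = scheme$category[[tg]],
         level = if (is.na(lev)) NULL else lev,
         domains = as.list(scheme$domains[[tg]] %||% character(0)))
  })
  jsonlite::write_json(list(tags = entries), path,
                       auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}

#' Map selected tags onto cognitive-functional domains
#'
#' Groups a set of selected discriminator tags by the cognitive domains
#' annotated in the scheme.  A tag annotated with several domains
#' appears under each of them; tags without any domain annotation are
#' listed under `"unmapped"`.  Output order is deterministic: domains in
#' the fixed order of [cognitive_domains()], tags within each domain in
#' scheme order.
#'
#' @param selected_tags Character vector of tag identifiers (all must be
#'   present in `scheme`).
#' @param scheme A [tag_scheme].
#' @return An object of class `domain_report`: a named list with one
#'   character vector per domain plus `"unmapped"`.
#' @export
#' @examples
#' sc <- default_tag_scheme()
#' map_to_domains("Clause complexes-parallel clauses", sc)
map_to_domains <- function(selected_tags, scheme) {
  stopifnot(inherits(scheme, "tag_scheme"))
  selected_tags <- as.character(selected_tags)
  unknown <- setdiff(selected_tags, scheme$tags)
  if (length(unknown))
    stop("tag(s) not in scheme: ", paste(unknown, collapse = ", "))
  # scheme order, deduplicated
  sel <- scheme$tags[scheme$tags %in% selected_tags]
  report <- stats::setNames(
    lapply(cognitive_domains(), function(d) {
      sel[vapply(sel, function(tg) d %in% (scheme$domains[[tg]] %||% character(0)),
                 logical(1))]
    }),
    cognitive_domains())
  report$unmapped <-
    sel[vapply(sel, function(tg) length(scheme$domains[[tg]] %||% character(0)) == 0L,
               logical(1))]
  structure(report, class = "domain_report")
}

#' @export
print.domain_report <- function(x, ...) {
  for (d in names(x)) {
    cat(d, " (", length(x[[d]]), ")\n", sep = "")
    for (tg in x[[d]]) cat("  - ", tg, "\n", sep = "")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
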