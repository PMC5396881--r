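# Partition a drug's article set into DDI-related (group A) and
# DDI-unrelated (group B) literature, plus the record-level filters.

#' Partition articles into DDI-related and DDI-unrelated groups
#'
#' An article belongs to group A (DDI-related) iff at least one of its MeSH
#' descriptors is an interaction descriptor; matching is on the bare
#' descriptor — qualifiers and abstract text never enter the decision.
#' Every article lands in exactly one group, so the result is a true
#' bipartition of the input.
#'
#' @param articles Article tibble (see [read_medline()]).
#' @param drug Query drug descriptor (provenance only; the drug's own
#'   descriptor may appear in either group).
#' @param interaction_terms Interaction descriptor set; defaults to the
#'   eight descriptors of [ddi_interaction_terms()].
#' @param filters Optional named list recording upstream filters (date
#'   cutoff, review exclusion) for provenance.
#' @return Object of class `ddi_corpus`: list with `drug`, `group_a`,
#'   `group_b` (article tibbles) and `filters`.
#' @export
partition_corpus <- function(articles, drug = NULL,
                             interaction_terms = ddi_interaction_terms(),
                             filters = list()) {
  dup <- articles$pmid[duplicated(articles$pmid)]
  if (length(dup)) stop("duplicate PMID in input: ", dup[1L])
  key <- norm_term(interaction_terms)
  in_a <- vapply(article_descriptors(articles), function(d) {
    any(norm_term(d) %in% key)
  }, NA)
  structure(
    list(
      drug = drug,
      group_a = articles[in_a, , drop = FALSE],
      group_b = articles[!in_a, , drop = FALSE],
      filters = modifyList(list(interaction_terms = interaction_terms), filters)
    ),
    class = "ddi_corpus"
  )
}

#' @export
print.ddi_corpus <- function(x, ...) {
  cat(sprintf(
    "<ddi_corpus>%s group A (DDI-related): %d articles; group B: %d articles\n",
    if (is.null(x$drug)) "" else paste0(" drug = ", x$drug, ";"),
    nrow(x$group_a), nrow(x$group_b)
  ))
  invisible(x)
}

#' @rdname partition_corpus
#' @param corpus A `ddi_corpus`.
#' @export
group_a <- function(corpus) corpus$group_a

#' @rdname partition_corpus
#' @export
group_b <- function(corpus) corpus$group_b

#' Drop review articles
#'
#' Removes every article whose publication types include "Review"
#' (case-insensitive). Idempotent. Used for the sensitivity analysis that
#' re-runs term identification on primary literature only.
#'
#' @param articles Article tibble.
#' @return Filtered article tibble.
#' @export
filter_reviews <- function(articles) {
  is_review <- vapply(articles$pub_types, function(pt) {
    any(stringr::str_to_lower(pt) == "review")
  }, NA)
  articles[!is_review, , drop = FALSE]
}

#' Apply the publication-date cutoff
#'
#' Retains articles published on or before `date_end` (inclusive).
#' Year-only records are compared by year alone; a record whose month is
#' known but day is not is compared at month precision. Articles with no
#' parseable year are excluded and reported with a message.
#'
#' @param articles Article tibble.
#' @param date_end A `Date` or ISO "YYYY-MM-DD" string.
#' @return Filtered article tibble.
#' @export
filter_by_date <- function(articles, date_end) {
  date_end <- as.Date(date_end)
  ey <- as.integer(format(date_end, "%Y"))
  em <- as.integer(format(date_end, "%m"))
  ed <- as.integer(format(date_end, "%d"))
  no_year <- is.na(articles$year)
  if (any(no_year)) {
    message(sum(no_year), " article(s) with missing year excluded: ",
            paste(articles$pmid[no_year], collapse = ", "))
  }
  y <- articles$year
  m <- articles$month
  d <- articles$day
  keep <- !no_year & (
    y < ey |
      (y == ey & (is.na(m) | m < em |
                    (m == em & (is.na(d) | d <= ed))))
  )
  articles[keep, , drop = FALSE]
}
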