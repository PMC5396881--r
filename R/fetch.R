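# Live retrieval from the NCBI E-utilities service, with an injectable
# transport so the pagination and caching logic is testable offline.

EUTILS_BASE <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils"

default_transport <- function(endpoint, params, retries = 3L) {
  url <- paste0(EUTILS_BASE, "/", endpoint, ".fcgi?",
                paste(names(params), vapply(params, utils::URLencode, "", reserved = TRUE),
                      sep = "=", collapse = "&"))
  for (attempt in seq_len(retries)) {
    res <- tryCatch(paste(readLines(url, warn = FALSE), collapse = "\n"),
                    error = function(e) e)
    if (!inherits(res, "error")) return(res)
    Sys.sleep(2^attempt)
  }
  stop("PubMed service unreachable after ", retries, " attempts: ",
       conditionMessage(res))
}

#' Fetch a drug's articles from PubMed
#'
#' Runs the query `"<drug> [MeSH Terms]"` (any literal query string is
#' accepted) through esearch/efetch with paged retrieval, parses the
#' PubMed XML pages, and keeps records with publication date on or before
#' `date_end` (inclusive; year-only records compared by year). Results are
#' cached as MEDLINE flat text keyed by `(query, date_end)` so reruns are
#' fully offline.
#'
#' @param query Query string; use [pubmed_drug_query()] for the standard
#'   drug query.
#' @param date_end Inclusive publication-date cutoff.
#' @param batch_size Records per efetch page (default 200).
#' @param cache_dir Directory for the offline cache; `NULL` disables
#'   caching.
#' @param transport Function `(endpoint, params) -> response text`; the
#'   default talks to NCBI with retry/backoff. Tests inject canned pages.
#' @return Article tibble.
#' @export
fetch_pubmed <- function(query, date_end, batch_size = 200L,
                         cache_dir = NULL, transport = default_transport) {
  stopifnot(nzchar(query))
  date_end <- as.Date(date_end)
  if (!is.null(cache_dir)) {
    key <- config_hash(list(query = query, date_end = as.character(date_end)))
    cache_file <- file.path(cache_dir, paste0("pubmed-", key, ".medline"))
    if (file.exists(cache_file)) {
      return(read_medline(cache_file))
    }
  }
  es <- xml2::read_xml(transport("esearch", list(
    db = "pubmed", term = query, retmax = "0", usehistory = "n"
  )))
  total <- as.integer(xml2::xml_text(xml2::xml_find_first(es, "//Count")))
  pages <- list()
  start <- 0L
  while (start < total) {
    page_ids <- xml2::xml_text(xml2::xml_find_all(
      xml2::read_xml(transport("esearch", list(
        db = "pubmed", term = query, retstart = as.character(start),
        retmax = as.character(batch_size)
      ))),
      "//IdList/Id"
    ))
    if (length(page_ids) == 0L) break
    xml <- transport("efetch", list(
      db = "pubmed", id = paste(page_ids, collapse = ","), retmode = "xml"
    ))
    pages[[length(pages) + 1L]] <- read_pubmed_xml(xml)
    start <- start + length(page_ids)
  }
  articles <- bind_rows(pages)
  if (is.null(articles) || nrow(articles) == 0L) {
    articles <- read_medline(character())
  }
  articles <- suppressMessages(filter_by_date(articles, date_end))
  if (!is.null(cache_dir) && nrow(articles) > 0L) {
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    write_medline(articles, cache_file)
  }
  articles
}

#' @rdname fetch_pubmed
#' @param drug Drug descriptor name.
#' @export
pubmed_drug_query <- function(drug) {
  sprintf("%s [MeSH Terms]", drug)
}
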