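# Reading and writing PubMed records: MEDLINE flat text and PubMed XML.
#
# Articles travel through the package as a tibble, one row per record:
#   pmid       character, unique
#   title      character
#   year/month/day  integer (month/day may be NA; year NA only if the DP
#                   field had no 4-digit year)
#   pub_types  list of character
#   abstract   character ("" when absent)
#   mesh       list of tibbles (descriptor, qualifiers <list>, major_topic)
#   substances list of character

article_tibble <- function(pmid = character(), title = character(),
                           year = integer(), month = integer(), day = integer(),
                           pub_types = list(), abstract = character(),
                           mesh = list(), substances = list()) {
  tibble(
    pmid = as.character(pmid), title = as.character(title),
    year = as.integer(year), month = as.integer(month), day = as.integer(day),
    pub_types = pub_types, abstract = as.character(abstract),
    mesh = mesh, substances = substances
  )
}

empty_mesh <- function() {
  tibble(descriptor = character(), qualifiers = list(), major_topic = logical())
}

#' Per-article MeSH descriptors
#'
#' Unique qualifier-stripped descriptor names for each article. This is the
#' unit all counting and matching in the pipeline operates on: the bare
#' descriptor, never the descriptor/subheading pair.
#'
#' @param articles Article tibble (see [read_medline()]).
#' @return List of character vectors, one per article.
#' @export
article_descriptors <- function(articles) {
  lapply(articles$mesh, function(m) unique(m$descriptor))
}

parse_mesh_heading <- function(x) {
  major <- stringr::str_detect(x, stringr::fixed("*"))
  parts <- stringr::str_split(stringr::str_remove_all(x, stringr::fixed("*")), stringr::fixed("/"))
  tibble(
    descriptor = stringr::str_trim(vapply(parts, `[`, "", 1L)),
    qualifiers = lapply(parts, function(p) stringr::str_trim(p[-1L])),
    major_topic = major
  )
}

parse_dp <- function(dp) {
  year <- suppressWarnings(as.integer(stringr::str_extract(dp, "\\b\\d{4}\\b")))
  mon <- match(stringr::str_to_title(stringr::str_extract(dp, "(?i)\\b[A-Za-z]{3}")), month.abb)
  day <- suppressWarnings(as.integer(stringr::str_extract(dp, "(?<=\\s)\\d{1,2}\\b(?!\\d)")))
  list(year = year, month = as.integer(mon), day = day)
}

# Split raw MEDLINE lines into per-record blocks of "TAG- value" fields,
# joining indented continuation lines with single spaces.
medline_fields <- function(lines) {
  lines <- lines[!(cumsum(nzchar(lines)) == 0L)]          # leading blanks
  rec_id <- cumsum(c(TRUE, !nzchar(lines[-length(lines)])))
  blocks <- split(lines, rec_id)
  blocks <- lapply(blocks, function(b) b[nzchar(b)])
  blocks <- blocks[vapply(blocks, length, 0L) > 0L]
  lapply(blocks, function(b) {
    is_cont <- stringr::str_detect(b, "^\\s")
    fid <- cumsum(!is_cont)
    vapply(split(b, fid), function(fl) {
      paste(stringr::str_trim(fl), collapse = " ")
    }, "")
  })
}

#' Read MEDLINE flat-text records
#'
#' Parses the tagged MEDLINE format (`PMID- `, `TI  - `, `DP  - `, `PT  - `,
#' `AB  - `, `MH  - `, `RN  - `/`NM  - `; indented continuation lines).
#' MeSH headings are split at `/` into descriptor and qualifiers and the
#' `*` major-topic marker is stripped into a logical flag.
#'
#' Records without a PMID are skipped, collected in the `problems` attribute
#' (a tibble with columns `record`, `issue`) and reported with a warning;
#' parsing continues. A date field without a 4-digit year yields `NA` year.
#'
#' @param path File path, or a character vector of lines.
#' @return Article tibble; attribute `problems` lists skipped records.
#' @export
read_medline <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  blocks <- medline_fields(lines)
  problems <- tibble(record = integer(), issue = character())
  rows <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    m <- stringr::str_match(blocks[[i]], "^([A-Z]{1,4}) *- (.*)$")
    tags <- m[, 2L]
    vals <- m[, 3L]
    keep <- !is.na(tags)
    tags <- tags[keep]
    vals <- vals[keep]
    first <- function(tag) {
      v <- vals[tags == tag]
      if (length(v)) v[1L] else NA_character_
    }
    pmid <- first("PMID")
    if (is.na(pmid) || !nzchar(pmid)) {
      problems <- bind_rows(problems, tibble(record = i, issue = "missing PMID"))
      next
    }
    dp <- parse_dp(first("DP"))
    mh <- vals[tags == "MH"]
    ab <- first("AB")
    ti <- first("TI")
    rows[[i]] <- article_tibble(
      pmid = pmid,
      title = if (is.na(ti)) "" else ti,
      year = dp$year, month = dp$month, day = dp$day,
      pub_types = list(unname(vals[tags == "PT"])),
      abstract = if (is.na(ab)) "" else ab,
      mesh = list(if (length(mh)) parse_mesh_heading(mh) else empty_mesh()),
      substances = list(unname(vals[tags %in% c("RN", "NM")]))
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0L) out <- article_tibble()
  out$title[is.na(out$title)] <- ""
  if (nrow(problems)) {
    warning(sprintf("%d MEDLINE record(s) skipped (see attr(., 'problems'))", nrow(problems)))
  }
  attr(out, "problems") <- problems
  out
}

format_dp <- function(year, month, day) {
  paste(c(
    if (!is.na(year)) year,
    if (!is.na(month)) month.abb[month],
    if (!is.na(day)) sprintf("%02d", day)
  ), collapse = " ")
}

format_mesh_heading <- function(mesh) {
  if (nrow(mesh) == 0L) return(character())
  paste0(
    ifelse(mesh$major_topic, "*", ""),
    mesh$descriptor,
    vapply(mesh$qualifiers, function(q) {
      if (length(q)) paste0("/", paste(q, collapse = "/")) else ""
    }, "")
  )
}

wrap_field <- function(tag, value) {
  sprintf("%-4s- %s", tag, value)
}

#' Write articles as MEDLINE flat text
#'
#' Inverse of [read_medline()]: the emitted text re-parses to an equal
#' article tibble. Articles violating the invariants (empty or duplicate
#' PMID, missing year) are refused with the offending PMID named.
#'
#' @param articles Article tibble.
#' @param path Output file path; omit to return the lines invisibly.
#' @return The MEDLINE lines, invisibly.
#' @export
write_medline <- function(articles, path = NULL) {
  bad <- articles$pmid[is.na(articles$pmid) | !nzchar(articles$pmid)]
  if (length(bad) || anyNA(articles$pmid)) {
    stop("article with empty PMID cannot be serialized")
  }
  dup <- articles$pmid[duplicated(articles$pmid)]
  if (length(dup)) stop("duplicate PMID in corpus: ", dup[1L])
  if (anyNA(articles$year)) {
    stop("article with missing year: PMID ", articles$pmid[which(is.na(articles$year))[1L]])
  }
  recs <- lapply(seq_len(nrow(articles)), function(i) {
    a <- articles[i, ]
    c(
      wrap_field("PMID", a$pmid),
      if (nzchar(a$title)) wrap_field("TI", a$title),
      wrap_field("DP", format_dp(a$year, a$month, a$day)),
      vapply(a$pub_types[[1L]], function(pt) wrap_field("PT", pt), ""),
      if (nzchar(a$abstract)) wrap_field("AB", a$abstract),
      vapply(a$substances[[1L]], function(s) wrap_field("NM", s), ""),
      vapply(format_mesh_heading(a$mesh[[1L]]), function(m) wrap_field("MH", m), ""),
      ""
    )
  })
  lines <- unlist(recs, use.names = FALSE) %||% character()
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read PubMed XML records
#'
#' Parses a `PubmedArticleSet` document into the same article tibble as
#' [read_medline()]; `DescriptorName/@MajorTopicYN` (or a `Y` on any
#' qualifier) maps to the major-topic flag. Malformed XML is a fatal error.
#'
#' @param path File path or XML string.
#' @return Article tibble.
#' @export
read_pubmed_xml <- function(path) {
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  rows <- lapply(arts, function(a) {
    cit <- xml2::xml_find_first(a, "./MedlineCitation")
    txt1 <- function(xp) {
      node <- xml2::xml_find_first(cit, xp)
      if (inherits(node, "xml_missing")) "" else xml2::xml_text(node)
    }
    mh_nodes <- xml2::xml_find_all(cit, "./MeshHeadingList/MeshHeading")
    mesh <- if (length(mh_nodes)) {
      bind_rows(lapply(mh_nodes, function(h) {
        desc <- xml2::xml_find_first(h, "./DescriptorName")
        quals <- xml2::xml_find_all(h, "./QualifierName")
        tibble(
          descriptor = xml2::xml_text(desc),
          qualifiers = list(xml2::xml_text(quals)),
          major_topic = identical(xml2::xml_attr(desc, "MajorTopicYN"), "Y") ||
            any(xml2::xml_attr(quals, "MajorTopicYN") %in% "Y")
        )
      }))
    } else {
      empty_mesh()
    }
    dp_year <- txt1("./Article/Journal/JournalIssue/PubDate/Year")
    dp_mon <- txt1("./Article/Journal/JournalIssue/PubDate/Month")
    dp_day <- txt1("./Article/Journal/JournalIssue/PubDate/Day")
    mon <- if (nzchar(dp_mon)) {
      m <- match(stringr::str_to_title(substr(dp_mon, 1L, 3L)), month.abb)
      if (is.na(m)) suppressWarnings(as.integer(dp_mon)) else m
    } else {
      NA_integer_
    }
    article_tibble(
      pmid = txt1("./PMID"),
      title = txt1("./Article/ArticleTitle"),
      year = if (nzchar(dp_year)) as.integer(dp_year) else NA_integer_,
      month = mon,
      day = if (nzchar(dp_day)) as.integer(dp_day) else NA_integer_,
      pub_types = list(xml2::xml_text(
        xml2::xml_find_all(cit, "./Article/PublicationTypeList/PublicationType")
      )),
      abstract = txt1("./Article/Abstract/AbstractText"),
      mesh = list(mesh),
      substances = list(xml2::xml_text(
        xml2::xml_find_all(cit, "./ChemicalList/Chemical/NameOfSubstance")
      ))
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) out <- article_tibble()
  attr(out, "problems") <- tibble(record = integer(), issue = character())
  out
}

#' Write articles as PubMed XML
#'
#' Emits a `PubmedArticleSet` document that [read_pubmed_xml()] parses back
#' to an equal article tibble.
#'
#' @inheritParams write_medline
#' @return The `xml2` document, invisibly.
#' @export
write_pubmed_xml <- function(articles, path = NULL) {
  doc <- xml2::xml_new_root("PubmedArticleSet")
  for (i in seq_len(nrow(articles))) {
    a <- articles[i, ]
    art <- xml2::xml_add_child(doc, "PubmedArticle")
    cit <- xml2::xml_add_child(art, "MedlineCitation")
    xml2::xml_add_child(cit, "PMID", a$pmid)
    anode <- xml2::xml_add_child(cit, "Article")
    jnode <- xml2::xml_add_child(anode, "Journal")
    inode <- xml2::xml_add_child(jnode, "JournalIssue")
    dnode <- xml2::xml_add_child(inode, "PubDate")
    if (!is.na(a$year)) xml2::xml_add_child(dnode, "Year", as.character(a$year))
    if (!is.na(a$month)) xml2::xml_add_child(dnode, "Month", month.abb[a$month])
    if (!is.na(a$day)) xml2::xml_add_child(dnode, "Day", sprintf("%02d", a$day))
    xml2::xml_add_child(anode, "ArticleTitle", a$title)
    if (nzchar(a$abstract)) {
      ab <- xml2::xml_add_child(anode, "Abstract")
      xml2::xml_add_child(ab, "AbstractText", a$abstract)
    }
    ptl <- xml2::xml_add_child(anode, "PublicationTypeList")
    for (pt in a$pub_types[[1L]]) xml2::xml_add_child(ptl, "PublicationType", pt)
    if (length(a$substances[[1L]])) {
      cl <- xml2::xml_add_child(cit, "ChemicalList")
      for (s in a$substances[[1L]]) {
        ch <- xml2::xml_add_child(cl, "Chemical")
        xml2::xml_add_child(ch, "NameOfSubstance", s)
      }
    }
    m <- a$mesh[[1L]]
    if (nrow(m)) {
      ml <- xml2::xml_add_child(cit, "MeshHeadingList")
      for (j in seq_len(nrow(m))) {
        h <- xml2::xml_add_child(ml, "MeshHeading")
        xml2::xml_add_child(h, "DescriptorName", m$descriptor[j],
                            MajorTopicYN = if (m$major_topic[j]) "Y" else "N")
        for (q in m$qualifiers[[j]]) {
          xml2::xml_add_child(h, "QualifierName", q, MajorTopicYN = "N")
        }
      }
    }
  }
  if (!is.null(path)) xml2::write_xml(doc, path)
  invisible(doc)
}
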