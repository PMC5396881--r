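# MeSH vocabulary: descriptor -> tree numbers, plus the drug/protein/
# phenomena classifier used to bucket candidate terms.

TREE_NUMBER_RE <- "^[A-Z][0-9]+(\\.[0-9]+)*$"

# Tree branches defining the protein and phenomena categories.
PROTEIN_BRANCHES <- c("D08", "D12.776")
PHENOMENA_BRANCHES <- c("G03", "G04", "G06", "G07")

#' The eight DDI interaction descriptors
#'
#' The MeSH descriptors whose presence marks an article as DDI-related:
#' drug interactions, the four agonism/antagonism descriptors, drug
#' synergism, and the food-drug / herb-drug interaction descriptors.
#'
#' @return Character vector of eight descriptor names.
#' @export
ddi_interaction_terms <- function() {
  c(
    "Drug Interactions", "Drug Agonism", "Drug Partial Agonism",
    "Drug Antagonism", "Drug Inverse Agonism", "Drug Synergism",
    "Food-Drug Interactions", "Herb-Drug Interactions"
  )
}

#' Construct a MeSH vocabulary
#'
#' @param descriptors Tibble with columns `descriptor` (character) and
#'   `tree_numbers` (list of character vectors, possibly empty).
#' @param drugs Character vector of drug descriptor names (e.g. the
#'   FDA-approved set present in MeSH); must be a subset of `descriptors`.
#' @param entry_terms Optional tibble (`synonym`, `descriptor`) for
#'   canonicalizing entry terms; `NULL` disables synonym resolution.
#' @return Object of class `mesh_vocab`.
#' @export
mesh_vocab <- function(descriptors, drugs = character(), entry_terms = NULL) {
  descriptors <- as_tibble(descriptors)
  stopifnot(all(c("descriptor", "tree_numbers") %in% names(descriptors)))
  dup <- descriptors$descriptor[duplicated(norm_term(descriptors$descriptor))]
  if (length(dup)) stop("duplicate descriptor: ", dup[1L])
  tn <- unlist(descriptors$tree_numbers, use.names = FALSE)
  bad <- tn[!grepl(TREE_NUMBER_RE, tn)]
  if (length(bad)) stop("malformed tree number: ", bad[1L])
  missing <- setdiff(norm_term(drugs), norm_term(descriptors$descriptor))
  if (length(missing)) stop("drug not among descriptors: ", missing[1L])
  structure(
    list(
      descriptors = descriptors,
      drugs = unique(as.character(drugs)),
      entry_terms = entry_terms
    ),
    class = "mesh_vocab"
  )
}

#' @export
print.mesh_vocab <- function(x, ...) {
  cat(sprintf(
    "<mesh_vocab> %d descriptors, %d drug terms, %s entry terms\n",
    nrow(x$descriptors), length(x$drugs),
    if (is.null(x$entry_terms)) "no" else nrow(x$entry_terms)
  ))
  invisible(x)
}

#' Read a MeSH ASCII descriptor file
#'
#' Parses the official descriptor distribution format: records separated by
#' `*NEWRECORD`, with `MH = ` (heading) and zero or more `MN = ` (tree
#' number) lines. Descriptors without any `MN` line are retained with an
#' empty tree list; a record carrying `MN` but no `MH` is a format error.
#'
#' @param path File path or character vector of lines.
#' @param drug_list Optional character vector (or path to a one-name-per-line
#'   file) of drug names to match against descriptors; see
#'   [set_drug_list()].
#' @return A [mesh_vocab()] object.
#' @export
read_mesh_ascii <- function(path, drug_list = NULL) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path, warn = FALSE) else path
  lines <- stringr::str_trim(lines, side = "right")
  rec_id <- cumsum(stringr::str_detect(lines, "^\\*NEWRECORD"))
  keep <- rec_id > 0L & !stringr::str_detect(lines, "^\\*NEWRECORD") & nzchar(lines)
  recs <- split(lines[keep], rec_id[keep])
  rows <- lapply(names(recs), function(id) {
    rec <- recs[[id]]
    mh <- stringr::str_match(rec, "^MH = (.*)$")[, 2L]
    mn <- stringr::str_match(rec, "^MN = (.*)$")[, 2L]
    mh <- mh[!is.na(mh)]
    mn <- mn[!is.na(mn)]
    if (length(mh) == 0L) {
      if (length(mn)) stop("record ", id, " has MN lines but no MH heading")
      return(NULL)
    }
    tibble(descriptor = mh[1L], tree_numbers = list(mn))
  })
  desc <- bind_rows(rows)
  if (is.null(desc) || nrow(desc) == 0L) {
    desc <- tibble(descriptor = character(), tree_numbers = list())
  }
  vocab <- mesh_vocab(desc)
  if (!is.null(drug_list)) vocab <- set_drug_list(vocab, drug_list)
  vocab
}

#' Read a simplified two-column vocabulary TSV
#'
#' Fixture-friendly dialect: header `descriptor<TAB>tree_numbers`, tree
#' numbers semicolon-joined (empty cell for none). Duplicate descriptor
#' rows are a fatal error.
#'
#' @inheritParams read_mesh_ascii
#' @return A [mesh_vocab()] object.
#' @export
read_mesh_tsv <- function(path, drug_list = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  stopifnot(identical(names(df)[1:2], c("descriptor", "tree_numbers")))
  dup <- df$descriptor[duplicated(norm_term(df$descriptor))]
  if (length(dup)) stop("duplicate descriptor row: ", dup[1L])
  desc <- tibble(
    descriptor = df$descriptor,
    tree_numbers = lapply(df$tree_numbers, function(x) {
      if (is.na(x) || !nzchar(x)) character() else stringr::str_trim(strsplit(x, ";", fixed = TRUE)[[1L]])
    })
  )
  vocab <- mesh_vocab(desc)
  if (!is.null(drug_list)) vocab <- set_drug_list(vocab, drug_list)
  vocab
}

#' Write the simplified vocabulary TSV
#'
#' Inverse of [read_mesh_tsv()] (round-trip property; drug list and entry
#' terms are not serialized in this dialect).
#'
#' @param vocab A `mesh_vocab`.
#' @param path Output path.
#' @export
write_mesh_tsv <- function(vocab, path) {
  df <- tibble(
    descriptor = vocab$descriptors$descriptor,
    tree_numbers = vapply(vocab$descriptors$tree_numbers, paste, "", collapse = ";")
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Attach a drug list to a vocabulary
#'
#' Matches names (e.g. the FDA-approved drug list) to descriptors by
#' normalized name; names absent from the vocabulary are dropped with a
#' message, mirroring how the published drug set was intersected with the
#' MeSH tree.
#'
#' @param vocab A `mesh_vocab`.
#' @param drug_list Character vector of names, or path to a one-per-line file.
#' @return The vocabulary with its `drugs` field set to the matched subset.
#' @export
set_drug_list <- function(vocab, drug_list) {
  if (length(drug_list) == 1L && file.exists(drug_list)) {
    drug_list <- readLines(drug_list, warn = FALSE)
  }
  drug_list <- drug_list[nzchar(stringr::str_trim(drug_list))]
  key <- norm_term(vocab$descriptors$descriptor)
  hit <- match(norm_term(drug_list), key)
  if (anyNA(hit)) {
    message(sum(is.na(hit)), " drug name(s) not found in the vocabulary; dropped")
  }
  vocab$drugs <- unique(vocab$descriptors$descriptor[hit[!is.na(hit)]])
  vocab
}

tree_under <- function(tree_numbers, branches) {
  prefixes <- paste0(branches, ".")
  vapply(tree_numbers, function(tns) {
    any(tns %in% branches) ||
      any(outer(tns, prefixes, function(t, p) substr(t, 1L, nchar(p)) == p))
  }, NA)
}

#' Classify descriptors into candidate categories
#'
#' Buckets each descriptor as one of `interaction`, `drug`, `protein`,
#' `phenomena`, or `other`, with that precedence: the eight interaction
#' descriptors first (they define the corpus partition and are never
#' candidates), then membership in the vocabulary's drug list, then any
#' tree number under D08 or D12.776 (proteins), then any under
#' G03/G04/G06/G07 (biological, physiological, diet/nutrition and
#' pharmacological phenomena). Tree membership is per dot-separated
#' segment, so D12.77 is not under D12.776. Unknown descriptors are
#' `other`.
#'
#' @param vocab A `mesh_vocab`.
#' @param terms Character vector of descriptor names.
#' @param interaction_terms Interaction descriptor set (override for
#'   sensitivity analyses).
#' @return Character vector of categories, same length as `terms`.
#' @export
classify_terms <- function(vocab, terms, interaction_terms = ddi_interaction_terms()) {
  key <- norm_term(terms)
  out <- rep("other", length(terms))
  idx <- match(key, norm_term(vocab$descriptors$descriptor))
  tns <- vector("list", length(terms))
  tns[!is.na(idx)] <- vocab$descriptors$tree_numbers[idx[!is.na(idx)]]
  tns[is.na(idx)] <- list(character())
  out[tree_under(tns, PHENOMENA_BRANCHES)] <- "phenomena"
  out[tree_under(tns, PROTEIN_BRANCHES)] <- "protein"
  out[key %in% norm_term(vocab$drugs)] <- "drug"
  out[key %in% norm_term(interaction_terms)] <- "interaction"
  out
}

#' Candidate terms from DDI-related articles
#'
#' The union of MeSH descriptors appearing in the supplied articles
#' (ordinarily group A of a partitioned corpus), bucketed by
#' [classify_terms()] and restricted to the requested categories. The query
#' drug's own descriptor is excluded: it is the corpus selector, present by
#' construction, and can carry no enrichment signal.
#'
#' @param vocab A `mesh_vocab`.
#' @param articles Article tibble (group A).
#' @param categories Categories to keep (default drug, protein, phenomena).
#' @param exclude Descriptors to drop (the query drug).
#' @return Tibble with columns `term`, `category`; buckets are disjoint.
#' @export
candidate_terms <- function(vocab, articles,
                            categories = c("drug", "protein", "phenomena"),
                            exclude = NULL) {
  terms <- unique(unlist(article_descriptors(articles), use.names = FALSE))
  if (is.null(terms)) terms <- character()
  if (!is.null(exclude)) terms <- terms[!norm_term(terms) %in% norm_term(exclude)]
  out <- tibble(term = terms, category = classify_terms(vocab, terms))
  out <- filter(out, .data$category %in% categories)
  arrange(out, .data$category, .data$term)
}
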