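# Synthetic MEDLINE corpora with planted ground truth. Every pipeline
# stage is testable offline against the generator's bookkeeping: group
# sizes, per-term per-group counts, review assignments, co-mention counts.

#' Specification for a synthetic corpus
#'
#' Describes the statistical structure the enrichment test assumes: term
#' inclusion is an independent Bernoulli draw per article, with prevalence
#' elevated in group A for enriched terms (`prevalence_a = min(1,
#' risk_ratio * prevalence_b)`). Optional pairwise co-mention excess is
#' planted with a marginal-preserving mixture: with probability `excess`
#' the pair is forced jointly present, otherwise both are drawn
#' independently at `(p - excess) / (1 - excess)`, so each term's marginal
#' prevalence is unchanged. Every group A article carries one interaction
#' descriptor drawn uniformly from the eight, and every article carries
#' the query drug descriptor (the corpus selector).
#'
#' @param n_a,n_b Group sizes (DDI-related / DDI-unrelated).
#' @param vocab_spec Named counts of decoy descriptors per category, e.g.
#'   `c(drug = 5, protein = 5, phenomena = 5, other = 5)`; decoys get
#'   auto-generated names and category-appropriate tree numbers and appear
#'   at `decoy_prevalence` in both groups (no enrichment).
#' @param planted_terms Tibble (`term`, `category`, `prevalence_b`,
#'   `risk_ratio`) of terms with controlled enrichment; `NULL` for none.
#' @param comention Tibble (`term_i`, `term_j`, `excess`) of excess joint
#'   probabilities planted in group A; `NULL` for none.
#' @param decoy_prevalence Per-group prevalence of decoy terms (default
#'   0.05).
#' @param review_fraction Fraction of each group flagged as review
#'   articles (`round(fraction * n)` per group; default 0).
#' @param years Publication-year range, inclusive.
#' @param query_drug Name of the query drug descriptor.
#' @param seed Integer seed (default 1).
#' @return List of class `generator_spec`.
#' @export
generator_spec <- function(n_a, n_b,
                           vocab_spec = c(drug = 5, protein = 5,
                                          phenomena = 5, other = 5),
                           planted_terms = NULL, comention = NULL,
                           decoy_prevalence = 0.05, review_fraction = 0,
                           years = c(2000L, 2015L), query_drug = "Querinib",
                           seed = 1L) {
  stopifnot(n_a >= 0, n_b >= 0, decoy_prevalence >= 0, decoy_prevalence <= 1,
            review_fraction >= 0, review_fraction <= 1)
  if (!is.null(planted_terms)) {
    planted_terms <- as_tibble(planted_terms)
    stopifnot(all(c("term", "category", "prevalence_b", "risk_ratio") %in%
                    names(planted_terms)),
              all(planted_terms$prevalence_b >= 0),
              all(planted_terms$prevalence_b <= 1),
              all(planted_terms$risk_ratio >= 1),
              all(planted_terms$category %in% c("drug", "protein",
                                                "phenomena", "other")))
  }
  spec <- structure(
    list(
      n_a = as.integer(n_a), n_b = as.integer(n_b),
      vocab_spec = vocab_spec, planted_terms = planted_terms,
      comention = if (is.null(comention)) NULL else as_tibble(comention),
      decoy_prevalence = decoy_prevalence,
      review_fraction = review_fraction,
      years = as.integer(years), query_drug = query_drug,
      seed = as.integer(seed)
    ),
    class = "generator_spec"
  )
  validate_comention(spec)
  spec
}

# Marginal prevalence table implied by the spec (before co-mention).
spec_prevalences <- function(spec) {
  decoys <- purrr::imap(spec$vocab_spec, function(k, cat) {
    if (k == 0) return(NULL)
    tibble(
      term = sprintf("Synthetic %s %02d", stringr::str_to_title(cat), seq_len(k)),
      category = cat,
      prevalence_b = spec$decoy_prevalence,
      prevalence_a = spec$decoy_prevalence,
      planted = FALSE
    )
  })
  planted <- if (!is.null(spec$planted_terms)) {
    mutate(spec$planted_terms,
           prevalence_a = pmin(1, .data$risk_ratio * .data$prevalence_b),
           planted = TRUE) %>%
      select("term", "category", "prevalence_b", "prevalence_a", "planted")
  }
  bind_rows(c(decoys, list(planted)))
}

validate_comention <- function(spec) {
  if (is.null(spec$comention) || nrow(spec$comention) == 0L) return(invisible())
  prev <- spec_prevalences(spec)
  for (i in seq_len(nrow(spec$comention))) {
    pair <- spec$comention[i, ]
    pa <- prev$prevalence_a[match(c(pair$term_i, pair$term_j), prev$term)]
    if (anyNA(pa)) stop("co-mention names unknown term: ", pair$term_i, " / ", pair$term_j)
    if (pair$excess > min(pa)) {
      stop(sprintf("co-mention excess %.3f for (%s, %s) exceeds marginal bound %.3f",
                   pair$excess, pair$term_i, pair$term_j, min(pa)))
    }
  }
  invisible()
}

# Tree numbers making each generated descriptor classify into its category.
decoy_tree_number <- function(category, i) {
  switch(category,
    drug = sprintf("D02.%03d", i),
    protein = if (i %% 2L) sprintf("D08.%03d", i) else sprintf("D12.776.%03d", i),
    phenomena = sprintf("%s.%03d", c("G03", "G04", "G06", "G07")[(i - 1L) %% 4L + 1L], i),
    other = sprintf("E05.%03d", i)
  )
}

spec_vocab <- function(spec, extra_drugs = character()) {
  prev <- spec_prevalences(spec)
  terms <- bind_rows(
    prev[c("term", "category")],
    tibble(term = c(spec$query_drug, extra_drugs),
           category = rep("drug", 1L + length(extra_drugs))),
    tibble(term = ddi_interaction_terms(), category = "interaction")
  )
  desc <- tibble(
    term = terms$term,
    tree_numbers = purrr::map2(terms$category, seq_len(nrow(terms)), function(cat, i) {
      if (cat == "interaction") "D26.255" else decoy_tree_number(cat, i)
    })
  )
  mesh_vocab(
    tibble(descriptor = desc$term, tree_numbers = desc$tree_numbers),
    drugs = terms$term[terms$category == "drug"]
  )
}

# Bernoulli inclusion matrix for one group, honoring co-mention excess.
draw_group <- function(n, prev_col, comention, prev) {
  k <- nrow(prev)
  m <- matrix(as.integer(runif(n * k) < rep(prev[[prev_col]], each = n)),
              nrow = n, ncol = k, dimnames = list(NULL, prev$term))
  if (!is.null(comention) && nrow(comention) && n > 0L) {
    for (k in seq_len(nrow(comention))) {
      i <- comention$term_i[k]
      j <- comention$term_j[k]
      e <- comention$excess[k]
      pi <- prev[[prev_col]][match(i, prev$term)]
      pj <- prev[[prev_col]][match(j, prev$term)]
      force <- runif(n) < e
      m[, i] <- ifelse(force, 1L, as.integer(runif(n) < (pi - e) / (1 - e)))
      m[, j] <- ifelse(force, 1L, as.integer(runif(n) < (pj - e) / (1 - e)))
    }
  }
  m
}

#' Generate a synthetic MEDLINE corpus
#'
#' @param spec A [generator_spec()].
#' @return List of class `synthetic_corpus` with `articles` (article
#'   tibble), `vocab` (a `mesh_vocab` covering every generated descriptor),
#'   and `truth`: group sizes, the per-term table (`term`, `category`,
#'   `planted`, prevalences, realized `count_a` / `count_b`), review PMIDs
#'   per group, the per-article interaction descriptor, and realized joint
#'   co-mention counts in group A.
#' @export
generate_corpus <- function(spec) {
  with_seed_if(spec$seed, generate_corpus_impl(spec))
}

generate_corpus_impl <- function(spec, extra_drugs = character()) {
  prev <- spec_prevalences(spec)
  vocab <- spec_vocab(spec, extra_drugs = extra_drugs)
  inc_a <- draw_group(spec$n_a, "prevalence_a", spec$comention, prev)
  inc_b <- draw_group(spec$n_b, "prevalence_b", NULL, prev)
  ia <- sample(ddi_interaction_terms(), spec$n_a, replace = TRUE)
  n <- spec$n_a + spec$n_b
  pmid <- sprintf("%07d", seq_len(n) + 1e6)
  group <- rep(c("A", "B"), c(spec$n_a, spec$n_b))
  n_rev_a <- round(spec$review_fraction * spec$n_a)
  n_rev_b <- round(spec$review_fraction * spec$n_b)
  rev_a <- sort(sample.int(spec$n_a, n_rev_a))
  rev_b <- sort(sample.int(spec$n_b, n_rev_b))
  is_review <- c(seq_len(spec$n_a) %in% rev_a, seq_len(spec$n_b) %in% rev_b)
  year <- spec$years[1L] +
    sample.int(spec$years[2L] - spec$years[1L] + 1L, n, replace = TRUE) - 1L
  month <- sample.int(12L, n, replace = TRUE)
  day <- sample.int(28L, n, replace = TRUE)
  inc <- rbind(inc_a, inc_b)
  mesh_of <- function(i) {
    terms <- c(
      spec$query_drug,
      if (group[i] == "A") ia[i],
      prev$term[inc[i, ] == 1L]
    )
    tibble(descriptor = terms,
           qualifiers = rep(list(character()), length(terms)),
           major_topic = rep(FALSE, length(terms)))
  }
  articles <- article_tibble(
    pmid = pmid,
    title = sprintf("Synthetic article %d on %s", seq_len(n), spec$query_drug),
    year = year, month = month, day = day,
    pub_types = lapply(is_review, function(r) c("Journal Article", if (r) "Review")),
    abstract = rep("", n),
    mesh = lapply(seq_len(n), mesh_of),
    substances = rep(list(character()), n)
  )
  comention_truth <- if (!is.null(spec$comention) && nrow(spec$comention)) {
    mutate(spec$comention,
           joint_count_a = purrr::map2_int(.data$term_i, .data$term_j, function(i, j) {
             sum(inc_a[, i] & inc_a[, j])
           }))
  }
  truth <- list(
    n_a = spec$n_a, n_b = spec$n_b,
    terms = mutate(prev,
                   count_a = as.integer(colSums(inc_a)[.data$term]),
                   count_b = as.integer(colSums(inc_b)[.data$term])),
    review_pmids_a = pmid[group == "A"][rev_a],
    review_pmids_b = pmid[group == "B"][rev_b],
    interaction_term = setNames(ia, pmid[group == "A"]),
    comention = comention_truth
  )
  structure(list(articles = articles, vocab = vocab, truth = truth,
                 spec = spec),
            class = "synthetic_corpus")
}

#' Generate a corpus with a designated drug pair
#'
#' Extends [generate_corpus()] for network tests: the partner drug is
#' added to the vocabulary's drug list, and the first `n_pair` group A
#' articles additionally co-mention the partner drug together with every
#' mechanism term, so those terms are connected to both the partner drug
#' and an interaction descriptor in the resulting pair network.
#'
#' @param spec A [generator_spec()].
#' @param partner_drug Partner drug descriptor name.
#' @param mechanism_terms Descriptors (protein/phenomena terms of the
#'   spec's vocabulary) forced into the pair articles.
#' @param n_pair Number of designated pair articles (must not exceed
#'   `spec$n_a`).
#' @return As [generate_corpus()]; `truth$pair_pmids` lists the designated
#'   articles.
#' @export
generate_pair_corpus <- function(spec, partner_drug, mechanism_terms,
                                 n_pair) {
  stopifnot(n_pair <= spec$n_a)
  prev <- spec_prevalences(spec)
  miss <- setdiff(mechanism_terms,
                  prev$term[prev$category %in% c("protein", "phenomena")])
  if (length(miss)) stop("mechanism term not a protein/phenomena term: ", miss[1L])
  corpus <- with_seed_if(spec$seed,
                         generate_corpus_impl(spec, extra_drugs = partner_drug))
  idx <- seq_len(n_pair)
  corpus$articles$mesh[idx] <- lapply(corpus$articles$mesh[idx], function(m) {
    add <- setdiff(c(partner_drug, mechanism_terms), m$descriptor)
    bind_rows(m, tibble(descriptor = add,
                        qualifiers = rep(list(character()), length(add)),
                        major_topic = rep(FALSE, length(add))))
  })
  corpus$truth$pair_pmids <- corpus$articles$pmid[idx]
  corpus$truth$terms <- mutate(
    corpus$truth$terms,
    count_a = term_article_count(corpus$articles[seq_len(spec$n_a), ],
                                 corpus$truth$terms$term)[.data$term]
  )
  corpus
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic_corpus> %d group A + %d group B articles, %d terms (%d planted)\n",
              x$truth$n_a, x$truth$n_b, nrow(x$truth$terms),
              sum(x$truth$terms$planted)))
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' MEDLINE flat-text corpus, vocabulary TSV, drug-list text file, and
#' ground-truth JSON, under a common stem.
#'
#' @param corpus A `synthetic_corpus`.
#' @param stem Path stem; writes `<stem>.medline`, `<stem>.vocab.tsv`,
#'   `<stem>.drugs.txt`, `<stem>.truth.json`.
#' @return Named character vector of the paths written.
#' @export
write_synthetic_corpus <- function(corpus, stem) {
  paths <- c(
    medline = paste0(stem, ".medline"),
    vocab = paste0(stem, ".vocab.tsv"),
    drugs = paste0(stem, ".drugs.txt"),
    truth = paste0(stem, ".truth.json")
  )
  write_medline(corpus$articles, paths[["medline"]])
  write_mesh_tsv(corpus$vocab, paths[["vocab"]])
  writeLines(corpus$vocab$drugs, paths[["drugs"]])
  truth <- corpus$truth
  truth$interaction_term <- as.list(truth$interaction_term)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
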