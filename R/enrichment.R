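# Resampling-based term enrichment: the core statistic. A candidate term's
# observed article count in group A is compared against the distribution of
# its count in repeated equal-size random subsets of group B; the tail
# probability comes from a Z-statistic against that resampled null.

#' Sampling configuration for the enrichment test
#'
#' @param n_resamples Number of random subsets drawn from group B (default
#'   1000).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param alpha Selection threshold on the p-value (default 0.1).
#' @param min_freq Selection threshold on the group A count; a term is kept
#'   only when its count is strictly greater than `min_freq` (default 5).
#' @param correction `"none"` (raw p-values, the default) or `"BH"`
#'   (Benjamini-Hochberg; selection then uses the adjusted p-value).
#' @return List of class `sampling_config`.
#' @export
sampling_config <- function(n_resamples = 1000L, seed = NULL, alpha = 0.1,
                            min_freq = 5L, correction = c("none", "BH")) {
  stopifnot(n_resamples >= 1L, alpha > 0, alpha <= 1, min_freq >= 0L)
  structure(
    list(
      n_resamples = as.integer(n_resamples),
      seed = if (is.null(seed)) NULL else as.integer(seed),
      alpha = alpha,
      min_freq = as.integer(min_freq),
      correction = match.arg(correction)
    ),
    class = "sampling_config"
  )
}

#' Count articles containing each term
#'
#' Document-level presence: an article contributes at most once per term
#' regardless of how many qualified headings repeat the descriptor.
#'
#' @param articles Article tibble.
#' @param terms Character vector of descriptors.
#' @return Named integer vector of counts, one per term.
#' @export
term_article_count <- function(articles, terms) {
  inc <- build_incidence(articles, terms)
  setNames(as.integer(colSums(inc)), terms)
}

#' Resampled null distribution of term counts
#'
#' Draws `cfg$n_resamples` subsets of `sample_size` articles from group B,
#' uniformly without replacement within each draw (with replacement across
#' draws), and counts every term in every subset. One shared set of draws
#' serves all terms, preserving their cross-term correlation. The null mean
#' and SD are the sample mean and sample standard deviation (n - 1
#' denominator) of the per-draw counts; for a term present in K of N group
#' B articles they converge to the hypergeometric mean and SD of sampling
#' `sample_size` from N.
#'
#' @param group_b Article tibble (group B).
#' @param terms Character vector of descriptors.
#' @param sample_size Articles per draw; in pipeline use, `|group A|`. Must
#'   not exceed `nrow(group_b)`.
#' @param cfg A [sampling_config()].
#' @return List with `stats` (tibble: term, null_mean, null_sd) and
#'   `resamples` (n_resamples x terms integer matrix of per-draw counts).
#' @export
null_distribution <- function(group_b, terms, sample_size,
                              cfg = sampling_config()) {
  n_b <- nrow(group_b)
  if (sample_size > n_b) {
    stop(sprintf("sample_size (%d) exceeds group B size (%d)", sample_size, n_b))
  }
  inc <- build_incidence(group_b, terms)
  counts <- with_seed_if(cfg$seed, {
    idx <- replicate(cfg$n_resamples, sample.int(n_b, sample_size))
    draw <- rep(seq_len(cfg$n_resamples), each = sample_size)
    m <- rowsum(inc[as.vector(idx), , drop = FALSE], draw, reorder = TRUE)
    dimnames(m) <- list(NULL, terms)
    m
  })
  sds <- apply(counts, 2L, stats::sd)
  list(
    stats = tibble(
      term = terms,
      null_mean = as.numeric(colMeans(counts)),
      null_sd = unname(ifelse(is.na(sds), 0, sds))
    ),
    resamples = counts
  )
}

#' Z-statistic and one-sided p-value against a resampled null
#'
#' `z = (count - null_mean) / null_sd`; the p-value is the upper tail of
#' the standard normal, matching the directional hypothesis that the term
#' is MORE frequent in DDI-related articles (depletion is never
#' significant). A degenerate null (`null_sd = 0`) yields p = 0 when the
#' observed count exceeds the null mean and p = 1 otherwise, with an
#' infinite z reported as a sentinel.
#'
#' @param count Observed count(s) in group A.
#' @param null_mean,null_sd Null moments from [null_distribution()].
#' @return Tibble with columns `z`, `p_value`.
#' @export
z_pvalue <- function(count, null_mean, null_sd) {
  stopifnot(all(null_sd >= 0))
  n <- max(length(count), length(null_mean), length(null_sd))
  count <- rep_len(count, n)
  null_mean <- rep_len(null_mean, n)
  null_sd <- rep_len(null_sd, n)
  z <- ifelse(null_sd > 0, (count - null_mean) / null_sd,
              ifelse(count > null_mean, Inf, -Inf))
  p <- ifelse(null_sd > 0, pnorm(z, lower.tail = FALSE),
              ifelse(count > null_mean, 0, 1))
  tibble(z = z, p_value = p)
}

#' Identify DDI-enriched MeSH terms
#'
#' The full enrichment test: candidate terms are extracted from group A and
#' bucketed into drug / protein / phenomena categories, counted in group A,
#' and tested against one shared resampled null built from group B with
#' subsets of size `|group A|`. A term is selected when its group A count
#' strictly exceeds `cfg$min_freq` and its p-value is below `cfg$alpha`.
#'
#' @param corpus A `ddi_corpus` from [partition_corpus()].
#' @param vocab A `mesh_vocab`.
#' @param categories Candidate categories (default drug, protein,
#'   phenomena); the query drug's own descriptor is excluded.
#' @param cfg A [sampling_config()].
#' @return Tibble of class `ddi_enrichment`, sorted by ascending p-value
#'   (ties: descending count, then term), with columns `term`, `category`,
#'   `count_a`, `null_mean`, `null_sd`, `z`, `p_value`
#'   (plus `p_adjusted` under BH correction) and `selected`.
#' @export
ddi_enrich <- function(corpus, vocab,
                       categories = c("drug", "protein", "phenomena"),
                       cfg = sampling_config()) {
  n_a <- nrow(corpus$group_a)
  n_b <- nrow(corpus$group_b)
  stopifnot(n_a >= 1L)
  if (n_b < n_a) {
    stop(sprintf("group B (%d) smaller than group A (%d): null undefined", n_b, n_a))
  }
  cand <- candidate_terms(vocab, corpus$group_a, categories = categories,
                          exclude = corpus$drug)
  if (nrow(cand) == 0L) {
    res <- tibble(term = character(), category = character(),
                  count_a = integer(), null_mean = numeric(),
                  null_sd = numeric(), z = numeric(), p_value = numeric(),
                  selected = logical())
    return(new_ddi_enrichment(res, corpus, cfg))
  }
  counts <- term_article_count(corpus$group_a, cand$term)
  null <- null_distribution(corpus$group_b, cand$term, sample_size = n_a, cfg = cfg)
  res <- cand %>%
    mutate(count_a = as.integer(counts[.data$term])) %>%
    left_join(null$stats, by = "term")
  res <- bind_cols(res, z_pvalue(res$count_a, res$null_mean, res$null_sd))
  if (cfg$correction == "BH") {
    res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
    res$selected <- res$count_a > cfg$min_freq & res$p_adjusted < cfg$alpha
  } else {
    res$selected <- res$count_a > cfg$min_freq & res$p_value < cfg$alpha
  }
  res <- arrange(res, .data$p_value, desc(.data$count_a), .data$term)
  new_ddi_enrichment(res, corpus, cfg)
}

new_ddi_enrichment <- function(res, corpus, cfg) {
  structure(
    res,
    class = c("ddi_enrichment", class(tibble())),
    drug = corpus$drug,
    n_a = nrow(corpus$group_a),
    n_b = nrow(corpus$group_b),
    config = cfg
  )
}

#' @export
tidy.ddi_enrichment <- function(x, ...) {
  as_tibble(unclass_enrichment(x))
}

unclass_enrichment <- function(x) {
  attr(x, "drug") <- NULL
  attr(x, "n_a") <- NULL
  attr(x, "n_b") <- NULL
  attr(x, "config") <- NULL
  class(x) <- class(tibble())
  x
}

#' @export
glance.ddi_enrichment <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(
    n_a = attr(x, "n_a"),
    n_b = attr(x, "n_b"),
    n_candidates = nrow(x),
    n_selected = sum(x$selected),
    n_drug = sum(x$selected & x$category == "drug"),
    n_protein = sum(x$selected & x$category == "protein"),
    n_phenomena = sum(x$selected & x$category == "phenomena"),
    n_resamples = cfg$n_resamples,
    alpha = cfg$alpha,
    min_freq = cfg$min_freq
  )
}

#' @export
autoplot.ddi_enrichment <- function(object, ...) {
  df <- tidy(object)
  df$neg_log10_p <- -log10(pmax(df$p_value, 1e-300))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count_a, y = .data$neg_log10_p,
                                   colour = .data$category,
                                   shape = .data$selected)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "articles in group A containing the term",
      y = expression(-log[10] ~ p),
      title = "DDI-enriched MeSH terms",
      subtitle = sprintf("group A = %d, group B = %d articles",
                         attr(object, "n_a"), attr(object, "n_b"))
    )
}

#' Write an enrichment table as TSV
#'
#' Columns term, category, count_a, null_mean, null_sd, z, p_value,
#' selected (and p_adjusted when present); a `# config_hash:` header
#' comment carries the configuration fingerprint.
#'
#' @param x A `ddi_enrichment`.
#' @param path Output path.
#' @param hash Optional configuration hash for the header.
#' @export
write_enrichment_tsv <- function(x, path, hash = NULL) {
  hash <- hash %||% config_hash(attr(x, "config"))
  writeLines(sprintf("# config_hash: %s", hash), path)
  readr::write_tsv(tidy(x), path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}
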