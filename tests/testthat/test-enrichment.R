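# Exact oracles for the resampled null: exhaustive subset enumeration and
# the closed-form hypergeometric moments.
enumerate_null_moments <- function(present, sample_size) {
  n <- length(present)
  subsets <- utils::combn(n, sample_size)
  counts <- apply(subsets, 2L, function(idx) sum(present[idx]))
  # population moments: every subset is equally likely
  c(mean = mean(counts), sd = sqrt(mean((counts - mean(counts))^2)))
}

hyper_moments <- function(N, K, n) {
  p <- K / N
  c(mean = n * p, sd = sqrt(n * p * (1 - p) * (N - n) / (N - 1)))
}

test_that("term counting is document-level presence", {
  arts <- make_articles(list(
    c("X/metabolism", "X/blood", "Y"),
    "Y",
    "Z"
  ))
  counts <- term_article_count(arts, c("X", "Y", "Absent"))
  expect_equal(unname(counts), c(1L, 2L, 0L))
  corp <- generate_corpus(generator_spec(n_a = 25, n_b = 25,
                                         decoy_prevalence = 0.2, seed = 4))
  truth <- corp$truth$terms
  counts <- term_article_count(corp$articles, truth$term)
  expect_equal(unname(counts), truth$count_a + truth$count_b)
})

test_that("resampled null matches exhaustive enumeration and the hypergeometric law", {
  # 10 group B articles, term present in 4; subsets of 5
  present <- c(rep(1L, 4L), rep(0L, 6L))
  arts <- make_articles(lapply(present, function(x) if (x) c("T", "F") else "F"))
  enum <- enumerate_null_moments(present, 5L)
  hyp <- hyper_moments(10, 4, 5)
  expect_equal(unname(enum["mean"]), unname(hyp["mean"]))           # 2.0
  expect_equal(unname(enum["sd"]), unname(hyp["sd"]), tolerance = 1e-12)  # ~0.8165
  null <- null_distribution(arts, c("T", "F"), sample_size = 5L,
                            cfg = sampling_config(n_resamples = 1000, seed = 2))
  est <- null$stats[null$stats$term == "T", ]
  se_mean <- hyp["sd"] / sqrt(1000)
  expect_lt(abs(est$null_mean - hyp["mean"]), 3 * se_mean)
  expect_lt(abs(est$null_sd - hyp["sd"]), 0.1)
  # a term present in every article is drawn with certainty
  expect_equal(null$stats$null_mean[null$stats$term == "F"], 5)
  expect_equal(null$stats$null_sd[null$stats$term == "F"], 0)
  expect_true(all(null$resamples[, "F"] == 5L))
})

test_that("null resampling is reproducible and refuses oversized draws", {
  arts <- make_articles(rep(list(c("T")), 8L))
  cfg <- sampling_config(n_resamples = 50, seed = 11)
  n1 <- null_distribution(arts, "T", 4L, cfg)
  n2 <- null_distribution(arts, "T", 4L, cfg)
  expect_identical(n1$resamples, n2$resamples)
  expect_error(null_distribution(arts, "T", 9L, cfg), "exceeds group B size")
})

test_that("Z p-values follow the one-sided upper tail with degenerate-null sentinels", {
  expect_equal(z_pvalue(2, 2, 1), tibble::tibble(z = 0, p_value = 0.5))
  # independent erf-based computation of the normal tail
  zp <- z_pvalue(4, 2.0, 0.8165)
  z_expected <- (4 - 2.0) / 0.8165
  p_erf <- pracma::erfc(z_expected / sqrt(2)) / 2
  expect_equal(zp$z, z_expected)
  expect_equal(zp$p_value, p_erf, tolerance = 1e-12)
  expect_equal(round(zp$p_value, 4), 0.0072)
  # depletion is never significant
  expect_gt(z_pvalue(0, 5, 1)$p_value, 0.99)
  # degenerate null
  expect_equal(z_pvalue(3, 2, 0), tibble::tibble(z = Inf, p_value = 0))
  expect_equal(z_pvalue(2, 2, 0), tibble::tibble(z = -Inf, p_value = 1))
  expect_equal(z_pvalue(1, 2, 0), tibble::tibble(z = -Inf, p_value = 1))
})

test_that("p-values are monotone non-increasing in the observed count", {
  counts <- 0:30
  p <- z_pvalue(counts, 12.3, 2.1)$p_value
  expect_true(all(diff(p) <= 0))
})

test_that("planted enrichment is detected and the selection rule is strict", {
  spec <- generator_spec(
    n_a = 200, n_b = 1000,
    vocab_spec = c(drug = 5, protein = 5, phenomena = 5, other = 5),
    planted_terms = tibble::tibble(
      term = sprintf("Planted Protein %02d", 1:5),
      category = "protein", prevalence_b = 0.05, risk_ratio = 4
    ),
    decoy_prevalence = 0.05, seed = 101
  )
  corp <- generate_corpus(spec)
  pc <- partition_corpus(corp$articles, drug = spec$query_drug)
  enr <- ddi_enrich(pc, corp$vocab, cfg = sampling_config(seed = 102))
  planted <- enr[enr$term %in% spec$planted_terms$term, ]
  expect_equal(nrow(planted), 5L)
  expect_true(all(planted$selected))
  # results sorted by ascending p, candidates exclude the query drug
  expect_true(all(diff(enr$p_value) >= 0))
  expect_false(spec$query_drug %in% enr$term)
  # strict min_freq: a term must exceed the cutoff, equality fails
  fake <- partition_corpus(make_articles(list(
    c("Drug Interactions", "T"), c("Drug Interactions", "T"),
    c("Drug Interactions", "T"), c("Drug Interactions", "T"),
    c("Drug Interactions", "T"),
    "U", "U", "U", "U", "U", "U", "U", "U", "U", "U"
  )))
  vocab <- mesh_vocab(tibble::tibble(descriptor = c("T", "U"),
                                     tree_numbers = list("D08.5", "D08.6")))
  enr2 <- ddi_enrich(fake, vocab, cfg = sampling_config(seed = 1))
  expect_equal(enr2$count_a[enr2$term == "T"], 5L)
  expect_false(enr2$selected[enr2$term == "T"])   # count == min_freq, not >
})

test_that("fixed seeds give bit-identical enrichment tables", {
  corp <- generate_corpus(generator_spec(n_a = 30, n_b = 120, seed = 55))
  pc <- partition_corpus(corp$articles, drug = "Querinib")
  cfg <- sampling_config(n_resamples = 200, seed = 9)
  e1 <- ddi_enrich(pc, corp$vocab, cfg = cfg)
  e2 <- ddi_enrich(pc, corp$vocab, cfg = cfg)
  expect_identical(tidy(e1), tidy(e2))
})

test_that("p-values are calibrated for the null the resampling actually tests", {
  # When the observed count itself arises as a size-n_a draw from group B
  # (the exchangeable null of the resampling scheme), upper-tail p-values
  # are uniform up to count discreteness.
  set.seed(77)
  arts <- make_articles(lapply(stats::runif(400) < 0.3, function(x) if (x) "T" else "F"))
  null <- null_distribution(arts, "T", sample_size = 100L,
                            cfg = sampling_config(n_resamples = 2000, seed = 78))
  mu <- null$stats$null_mean
  sd <- null$stats$null_sd
  # draw observed counts by the same subset mechanism the null resamples
  present <- vapply(arts$mesh, function(m) "T" %in% m$descriptor, NA)
  counts <- vapply(1:500, function(i) sum(present[sample.int(400, 100)]), 0L)
  p <- z_pvalue(counts, mu, sd)$p_value
  # mean of a Uniform(0,1) sample of 500 is within ~3.9 SE
  expect_lt(abs(mean(p) - 0.5), 0.05)
  expect_gt(mean(p < 0.1), 0.05)
  expect_lt(mean(p < 0.1), 0.16)
})

test_that("BH correction tightens selection without changing the ranking", {
  corp <- generate_corpus(generator_spec(n_a = 40, n_b = 200,
                                         decoy_prevalence = 0.3, seed = 61))
  pc <- partition_corpus(corp$articles, drug = "Querinib")
  raw <- ddi_enrich(pc, corp$vocab, cfg = sampling_config(seed = 2))
  bh <- ddi_enrich(pc, corp$vocab,
                   cfg = sampling_config(seed = 2, correction = "BH"))
  expect_equal(bh$p_adjusted, stats::p.adjust(bh$p_value, "BH"))
  expect_true(all(bh$term[bh$selected] %in% raw$term[raw$selected]))
  expect_identical(raw$term, bh$term)
})
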