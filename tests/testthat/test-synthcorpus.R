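test_that("generator self-audit: pipeline counts equal the truth record exactly", {
  spec <- generator_spec(
    n_a = 200, n_b = 400,
    vocab_spec = c(drug = 5, protein = 5, phenomena = 5, other = 5),
    planted_terms = tibble::tibble(
      term = sprintf("Planted Term %02d", 1:10),
      category = rep(c("drug", "protein"), 5),
      prevalence_b = 0.05, risk_ratio = 4
    ),
    review_fraction = 0.25, seed = 71
  )
  corp <- generate_corpus(spec)
  pc <- partition_corpus(corp$articles)
  expect_equal(nrow(group_a(pc)), spec$n_a)
  expect_equal(nrow(group_b(pc)), spec$n_b)
  truth <- corp$truth$terms
  expect_equal(unname(term_article_count(group_a(pc), truth$term)),
               truth$count_a)
  expect_equal(unname(term_article_count(group_b(pc), truth$term)),
               truth$count_b)
  n_rev <- length(c(corp$truth$review_pmids_a, corp$truth$review_pmids_b))
  expect_equal(nrow(corp$articles) - nrow(filter_reviews(corp$articles)), n_rev)
  expect_equal(n_rev, round(0.25 * 200) + round(0.25 * 400))
  # every group A article carries exactly one planted interaction descriptor
  ia <- corp$truth$interaction_term
  expect_setequal(names(ia), group_a(pc)$pmid)
  expect_true(all(ia %in% ddi_interaction_terms()))
})

test_that("empirical prevalences are within 3 binomial SE of the spec", {
  spec <- generator_spec(n_a = 200, n_b = 1000,
                         planted_terms = tibble::tibble(
                           term = "Hot Protein", category = "protein",
                           prevalence_b = 0.05, risk_ratio = 4),
                         decoy_prevalence = 0.05, seed = 72)
  corp <- generate_corpus(spec)
  truth <- corp$truth$terms
  se_a <- sqrt(truth$prevalence_a * (1 - truth$prevalence_a) / spec$n_a)
  se_b <- sqrt(truth$prevalence_b * (1 - truth$prevalence_b) / spec$n_b)
  expect_true(all(abs(truth$count_a / spec$n_a - truth$prevalence_a) <= 3 * se_a))
  expect_true(all(abs(truth$count_b / spec$n_b - truth$prevalence_b) <= 3 * se_b))
  expect_equal(truth$prevalence_a[truth$term == "Hot Protein"], 0.2)
})

test_that("prevalence realizations are unbiased across seeds", {
  errs <- vapply(1:60, function(s) {
    corp <- generate_corpus(generator_spec(
      n_a = 0, n_b = 50, vocab_spec = c(drug = 1, protein = 0,
                                        phenomena = 0, other = 0),
      decoy_prevalence = 0.2, seed = s
    ))
    corp$truth$terms$count_b / 50 - 0.2
  }, 0)
  se <- sqrt(0.2 * 0.8 / (50 * 60))
  expect_lt(abs(mean(errs)), 3 * se)
})

test_that("degenerate specs behave: empty group A and the certified null corpus", {
  corp0 <- generate_corpus(generator_spec(n_a = 0, n_b = 12, seed = 2))
  expect_equal(nrow(group_a(partition_corpus(corp0$articles))), 0L)
  null_spec <- generator_spec(n_a = 10, n_b = 20,
                              planted_terms = tibble::tibble(
                                term = "Flat Term", category = "protein",
                                prevalence_b = 0.3, risk_ratio = 1))
  corp <- generate_corpus(null_spec)
  truth <- corp$truth$terms
  expect_equal(truth$prevalence_a, truth$prevalence_b)
  expect_false(any(truth$planted & truth$prevalence_a > truth$prevalence_b))
})

test_that("generation is deterministic given the seed", {
  spec <- generator_spec(n_a = 20, n_b = 30, review_fraction = 0.1, seed = 5)
  c1 <- generate_corpus(spec)
  c2 <- generate_corpus(spec)
  expect_identical(as.data.frame(c1$articles), as.data.frame(c2$articles))
  expect_identical(c1$truth$terms, c2$truth$terms)
})

test_that("impossible co-mention excess is rejected at spec validation", {
  expect_error(
    generator_spec(n_a = 10, n_b = 10,
                   comention = tibble::tibble(term_i = "Synthetic Drug 01",
                                              term_j = "Synthetic Protein 01",
                                              excess = 0.5),
                   decoy_prevalence = 0.1),
    "exceeds marginal bound"
  )
  expect_error(
    generator_spec(n_a = 10, n_b = 10,
                   comention = tibble::tibble(term_i = "No Such Term",
                                              term_j = "Synthetic Protein 01",
                                              excess = 0.01)),
    "unknown term"
  )
})

test_that("co-mention excess preserves marginals and lifts the joint count", {
  spec <- generator_spec(
    n_a = 2000, n_b = 0,
    vocab_spec = c(drug = 2, protein = 2, phenomena = 0, other = 0),
    decoy_prevalence = 0.2,
    comention = tibble::tibble(term_i = "Synthetic Drug 01",
                               term_j = "Synthetic Protein 01", excess = 0.15),
    seed = 43
  )
  corp <- generate_corpus(spec)
  truth <- corp$truth$terms
  for (t in c("Synthetic Drug 01", "Synthetic Protein 01")) {
    expect_lt(abs(truth$count_a[truth$term == t] / 2000 - 0.2),
              3 * sqrt(0.2 * 0.8 / 2000))
  }
  # joint probability = excess + (1 - excess) p_i' p_j' >> independent p^2
  joint <- corp$truth$comention$joint_count_a / 2000
  expect_gt(joint, 0.12)
})

test_that("pair corpora plant the designated co-mention articles", {
  spec <- generator_spec(n_a = 12, n_b = 8,
                         vocab_spec = c(drug = 1, protein = 2,
                                        phenomena = 1, other = 0),
                         seed = 3)
  corp <- generate_pair_corpus(spec, "Partnerol",
                               mechanism_terms = "Synthetic Protein 01",
                               n_pair = 5L)
  expect_length(corp$truth$pair_pmids, 5L)
  pair_arts <- corp$articles[corp$articles$pmid %in% corp$truth$pair_pmids, ]
  for (d in article_descriptors(pair_arts)) {
    expect_true(all(c("Partnerol", "Synthetic Protein 01") %in% d))
  }
  pc <- partition_corpus(corp$articles, drug = spec$query_drug)
  net <- build_pair_network(pc, "Partnerol",
                            tibble::tibble(term = "Synthetic Protein 01",
                                           category = "protein"),
                            min_weight = 5L)
  w <- net$edges$weight[(net$edges$from == "Partnerol" &
                           net$edges$to == "Synthetic Protein 01") |
                          (net$edges$from == "Synthetic Protein 01" &
                             net$edges$to == "Partnerol")]
  expect_gte(w, 5L)
  # zero designated articles give an edgeless network at any threshold
  corp0 <- generate_pair_corpus(spec, "Partnerol",
                                mechanism_terms = "Synthetic Protein 01",
                                n_pair = 0L)
  pc0 <- partition_corpus(corp0$articles, drug = spec$query_drug)
  suppressWarnings(
    net0 <- build_pair_network(pc0, "Partnerol",
                               tibble::tibble(term = "Synthetic Protein 01",
                                              category = "protein"))
  )
  expect_equal(nrow(net0$edges), 0L)
})

test_that("written corpora parse back to the generated articles and vocabulary", {
  corp <- generate_corpus(generator_spec(n_a = 8, n_b = 12, seed = 9))
  stem <- file.path(withr::local_tempdir(), "synth")
  paths <- write_synthetic_corpus(corp, stem)
  expect_true(all(file.exists(paths)))
  expect_articles_equal(read_medline(paths[["medline"]]), corp$articles)
  vocab <- read_mesh_tsv(paths[["vocab"]], drug_list = paths[["drugs"]])
  expect_equal(vocab$descriptors, corp$vocab$descriptors)
  expect_setequal(vocab$drugs, corp$vocab$drugs)
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$n_a, 8L)
})
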