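# Fixture builders shared across test files. Everything is generated in
# code; no stored corpora.

# Minimal hand-built article tibble: `mesh` is a list of character vectors
# of descriptors (optionally "Desc/qual" strings, "*" marks major topic).
make_articles <- function(mesh, pmid = sprintf("%06d", seq_along(mesh)),
                          year = 2010L, pub_types = "Journal Article") {
  n <- length(mesh)
  tibble::tibble(
    pmid = pmid,
    title = sprintf("Article %s", pmid),
    year = rep_len(as.integer(year), n),
    month = rep(NA_integer_, n),
    day = rep(NA_integer_, n),
    pub_types = rep_len(list(pub_types), n),
    abstract = rep("", n),
    mesh = lapply(mesh, function(terms) {
      major <- grepl("*", terms, fixed = TRUE)
      parts <- strsplit(gsub("*", "", terms, fixed = TRUE), "/", fixed = TRUE)
      tibble::tibble(
        descriptor = vapply(parts, `[`, "", 1L),
        qualifiers = lapply(parts, `[`, -1L),
        major_topic = major
      )
    }),
    substances = rep(list(character()), n)
  )
}

# Small vocabulary: two drugs, two proteins, two phenomena, one other.
make_test_vocab <- function() {
  mesh_vocab(
    tibble::tibble(
      descriptor = c("Cyclosporine", "Rifampin", "Cytochrome P-450 CYP3A",
                     "P-Glycoprotein", "Biotransformation", "Drug Synergism",
                     "Kidney Calculi"),
      tree_numbers = list(
        "D03.383.129", "D04.345", c("D08.244.453", "D12.776.422"),
        "D12.776.157.530", "G03.495", "D26.255", "C12.777"
      )
    ),
    drugs = c("Cyclosporine", "Rifampin")
  )
}

drop_problems <- function(articles) {
  attr(articles, "problems") <- NULL
  articles
}

expect_articles_equal <- function(a, b) {
  expect_equal(as.data.frame(drop_problems(a)), as.data.frame(drop_problems(b)))
}
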