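# Shared helpers: term normalization and seeded evaluation.

#' Normalize a MeSH term for comparison
#'
#' Comparison key used everywhere terms are matched: NFC-normalized,
#' whitespace-trimmed, case-folded. Stored forms keep their canonical casing;
#' only comparisons go through this key.
#'
#' @param x Character vector of descriptor names.
#' @return Character vector of normalized keys.
#' @export
norm_term <- function(x) {
  x <- stringr::str_trim(enc2utf8(as.character(x)))
  x <- stringi::stri_trans_nfc(x)
  stringr::str_to_lower(x)
}

# Evaluate `expr` under `seed` (when non-NULL) without disturbing the
# caller's RNG state.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Stable short hash of a configuration, stamped into artifact headers.
config_hash <- function(config) {
  substr(rlang::hash(config), 1L, 12L)
}
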