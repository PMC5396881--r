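# End-to-end orchestration: load -> filter -> partition -> enrich ->
# co-occurrence -> ROC -> pair networks, with a run-summary JSON.

#' Read a flat key-value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment. List-valued keys
#' (`interaction_terms`, `categories`, `partner_drugs`) are
#' semicolon-separated. Recognized keys: `drug`, `corpus`, `vocab`,
#' `drug_list`, `gold_labels`, `out_dir`, `date_end`, `exclude_reviews`,
#' `n_resamples`, `seed`, `alpha`, `min_freq`, `correction`, `min_weight`,
#' `interaction_terms`, `partner_drugs`.
#'
#' @param path Config file path.
#' @return Named list (class `ddi_run_config`).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- stringr::str_trim(stringr::str_remove(lines, "#.*$"))
  lines <- lines[nzchar(lines)]
  m <- stringr::str_match(lines, "^([A-Za-z_]+)\\s*=\\s*(.*)$")
  if (anyNA(m[, 1L])) stop("malformed config line: ", lines[is.na(m[, 1L])][1L])
  cfg <- setNames(as.list(stringr::str_trim(m[, 3L])), m[, 2L])
  for (k in c("n_resamples", "seed", "min_freq", "min_weight")) {
    if (!is.null(cfg[[k]])) cfg[[k]] <- as.integer(cfg[[k]])
  }
  if (!is.null(cfg$alpha)) cfg$alpha <- as.numeric(cfg$alpha)
  if (!is.null(cfg$exclude_reviews)) {
    cfg$exclude_reviews <- tolower(cfg$exclude_reviews) %in% c("true", "1", "yes")
  }
  for (k in c("interaction_terms", "partner_drugs")) {
    if (!is.null(cfg[[k]])) {
      cfg[[k]] <- stringr::str_trim(strsplit(cfg[[k]], ";", fixed = TRUE)[[1L]])
    }
  }
  structure(cfg, class = "ddi_run_config")
}

load_vocab_any <- function(path, drug_list = NULL) {
  first <- readLines(path, n = 5L, warn = FALSE)
  if (any(stringr::str_detect(first, "^\\*NEWRECORD"))) {
    read_mesh_ascii(path, drug_list = drug_list)
  } else {
    read_mesh_tsv(path, drug_list = drug_list)
  }
}

#' Run the whole term-identification pipeline
#'
#' Executes load (or cached fetch) -> date/review filters -> group A/B
#' partition -> enrichment over drug, protein and phenomena candidates ->
#' drug x protein and drug x phenomena cross co-occurrence matrices with
#' clustering orders -> optional ROC validation -> optional pair networks,
#' writing every artifact under `config$out_dir` with the configuration
#' hash stamped in each TSV header. A stage failure aborts with the stage
#' named and removes this run's partial outputs.
#'
#' @param config A `ddi_run_config` (or named list with the same keys).
#' @param quiet Suppress the INFO narration of group sizes and filter
#'   attrition.
#' @return The run summary, invisibly: group sizes, selected-term counts
#'   per category, AUC (when labels are supplied), seed, config hash,
#'   output paths, timings.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  stage <- "configuration"
  on_fail <- function(e) {
    unlink(written)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }
  tryCatch({
    stage <- "load"
    articles <- if (!is.null(config$corpus)) {
      read_medline(config$corpus)
    } else {
      fetch_pubmed(pubmed_drug_query(config$drug), config$date_end,
                   cache_dir = config$cache_dir)
    }
    say("loaded %d articles", nrow(articles))
    stage <- "filter"
    if (!is.null(config$date_end)) {
      articles <- suppressMessages(filter_by_date(articles, config$date_end))
      say("after date cutoff %s: %d articles", config$date_end, nrow(articles))
    }
    if (isTRUE(config$exclude_reviews)) {
      articles <- filter_reviews(articles)
      say("after review exclusion: %d articles", nrow(articles))
    }
    stage <- "vocabulary"
    vocab <- load_vocab_any(config$vocab, drug_list = config$drug_list)
    stage <- "partition"
    ia_terms <- config$interaction_terms %||% ddi_interaction_terms()
    corpus <- partition_corpus(articles, drug = config$drug,
                               interaction_terms = ia_terms,
                               filters = list(date_end = config$date_end,
                                              exclude_reviews = isTRUE(config$exclude_reviews)))
    say("group A (DDI-related): %d; group B: %d",
        nrow(corpus$group_a), nrow(corpus$group_b))
    stage <- "enrichment"
    cfg <- sampling_config(
      n_resamples = config$n_resamples %||% 1000L,
      seed = config$seed,
      alpha = config$alpha %||% 0.1,
      min_freq = config$min_freq %||% 5L,
      correction = config$correction %||% "none"
    )
    enr <- ddi_enrich(corpus, vocab, cfg = cfg)
    p <- file.path(out_dir, "enrichment.tsv")
    write_enrichment_tsv(enr, p, hash = hash)
    written <- c(written, p)
    sel <- filter(tidy(enr), .data$selected)
    say("selected terms: %d drug, %d protein, %d phenomena",
        sum(sel$category == "drug"), sum(sel$category == "protein"),
        sum(sel$category == "phenomena"))
    stage <- "co-occurrence"
    orders <- list()
    for (cat in c("protein", "phenomena")) {
      rows <- sel$term[sel$category == "drug"]
      cols <- sel$term[sel$category == cat]
      if (length(rows) == 0L || length(cols) == 0L) next
      cc <- cross_cooccurrence(corpus$group_a, rows, cols)
      ccn <- suppressMessages(normalize_rows(cc))
      ord <- cluster_order(ccn)
      orders[[paste0("drug_x_", cat)]] <- ord
      p1 <- file.path(out_dir, sprintf("cooccurrence_drug_x_%s.tsv", cat))
      p2 <- file.path(out_dir, sprintf("cooccurrence_drug_x_%s_normalized.tsv", cat))
      write_matrix_tsv(cc, p1, hash = hash)
      write_matrix_tsv(ccn[ord$rows, ord$cols, drop = FALSE], p2, hash = hash)
      written <- c(written, p1, p2)
    }
    if (length(orders)) {
      p <- file.path(out_dir, "cluster_orders.json")
      jsonlite::write_json(orders, p, auto_unbox = FALSE)
      written <- c(written, p)
    }
    stage <- "roc"
    auc <- NULL
    if (!is.null(config$gold_labels)) {
      gold <- read_gold_labels(config$gold_labels)
      ranking <- tidy(enr) %>%
        left_join(gold, by = "term") %>%
        filter(!is.na(.data$label)) %>%
        rename(score = "p_value")
      if (length(unique(ranking$label)) == 2L) {
        pts <- roc_curve(ranking$score, ranking$label)
        auc <- roc_auc(pts)
        p <- file.path(out_dir, "roc_points.tsv")
        writeLines(sprintf("# config_hash: %s", hash), p)
        readr::write_tsv(pts, p, append = TRUE, col_names = TRUE, progress = FALSE)
        written <- c(written, p)
        say("ROC AUC = %.3f on %d labeled terms", auc, nrow(ranking))
      } else {
        say("gold labels cover a single class; ROC skipped")
      }
    }
    stage <- "network"
    for (partner in config$partner_drugs %||% character()) {
      net <- build_pair_network(corpus, partner, sel,
                                min_weight = config$min_weight %||% 2L,
                                interaction_terms = ia_terms)
      stem <- file.path(out_dir, paste0("network_", gsub("\\W+", "_", partner)))
      write_term_network(net, paste0(stem, ".graphml"), format = "graphml")
      write_term_network(net, paste0(stem, ".edges.tsv"), format = "tsv")
      written <- c(written, paste0(stem, ".graphml"), paste0(stem, ".edges.tsv"),
                   paste0(stem, ".edges.tsv.nodes.tsv"))
    }
    stage <- "summary"
    summary <- list(
      drug = config$drug,
      config_hash = hash,
      seed = cfg$seed,
      n_input = nrow(articles),
      n_group_a = nrow(corpus$group_a),
      n_group_b = nrow(corpus$group_b),
      n_candidates = nrow(enr),
      selected = list(
        drug = sum(sel$category == "drug"),
        protein = sum(sel$category == "protein"),
        phenomena = sum(sel$category == "phenomena")
      ),
      auc = auc,
      outputs = basename(written),
      timing_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
    p <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA, null = "null")
    invisible(summary)
  }, error = on_fail)
}
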