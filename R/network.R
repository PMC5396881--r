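# Weighted term network for a drug pair: nodes are selected MeSH terms
# (drugs, proteins, phenomena, interaction types), edges are co-occurrence
# counts within the pair's DDI-related articles.

new_ddi_network <- function(nodes, edges, provenance) {
  stopifnot(all(edges$weight > 0), !any(edges$from == edges$to))
  stopifnot(all(c(edges$from, edges$to) %in% nodes$term))
  structure(list(nodes = nodes, edges = edges, provenance = provenance),
            class = "ddi_network")
}

#' @export
print.ddi_network <- function(x, ...) {
  cat(sprintf("<ddi_network> %s + %s: %d nodes, %d edges (min_weight = %d, %d articles)\n",
              x$provenance$query_drug %||% "?", x$provenance$partner_drug,
              nrow(x$nodes), nrow(x$edges), x$provenance$min_weight,
              x$provenance$n_articles))
  invisible(x)
}

#' Build the term network for a drug pair
#'
#' Restricts group A (DDI-related articles) to those mentioning the partner
#' drug — by corpus construction these also mention the query drug and an
#' interaction descriptor — and connects every pair of network terms whose
#' co-occurrence count within that subset reaches `min_weight`. The node
#' set is the query and partner drugs, the selected protein and phenomena
#' terms, and whichever interaction descriptors occur in the subset; edge
#' weights are the raw co-occurrence counts. Terms a mechanism runs
#' through (e.g. a shared CYP enzyme) surface as nodes connected to both
#' the interaction descriptor and the partner drug.
#'
#' @param corpus A `ddi_corpus`.
#' @param partner_drug Partner drug descriptor (a selected drug term).
#' @param selected_terms Tibble (`term`, `category`) of selected terms,
#'   e.g. `dplyr::filter(tidy(enrichment), selected)`.
#' @param min_weight Minimum co-occurrence count for an edge (default 2,
#'   suppressing singleton co-mentions).
#' @param interaction_terms Interaction descriptor set.
#' @return A `ddi_network`: `nodes` (term, category), `edges`
#'   (from, to, weight), `provenance`.
#' @export
build_pair_network <- function(corpus, partner_drug, selected_terms,
                               min_weight = 2L,
                               interaction_terms = ddi_interaction_terms()) {
  desc <- article_descriptors(corpus$group_a)
  in_subset <- vapply(desc, function(d) norm_term(partner_drug) %in% norm_term(d), NA)
  subset <- corpus$group_a[in_subset, , drop = FALSE]
  if (nrow(subset) == 0L) {
    warning("partner drug '", partner_drug, "' absent from every group A article")
  }
  present <- unique(unlist(article_descriptors(subset), use.names = FALSE))
  ia_present <- interaction_terms[norm_term(interaction_terms) %in% norm_term(present)]
  sel <- filter(selected_terms, .data$category %in% c("protein", "phenomena"))
  nodes <- bind_rows(
    tibble(term = c(corpus$drug, partner_drug),
           category = rep("drug", length(c(corpus$drug, partner_drug)))),
    tibble(term = sel$term, category = sel$category),
    tibble(term = ia_present,
           category = rep("interaction", length(ia_present)))
  )
  nodes <- distinct(nodes, .data$term, .keep_all = TRUE)
  adj <- build_adjacency(build_incidence(subset, nodes$term))
  ut <- which(upper.tri(adj) & adj >= min_weight, arr.ind = TRUE)
  edges <- tibble(
    from = nodes$term[ut[, 1L]],
    to = nodes$term[ut[, 2L]],
    weight = as.integer(adj[ut])
  ) %>% arrange(.data$from, .data$to)
  new_ddi_network(nodes, edges, provenance = list(
    query_drug = corpus$drug, partner_drug = partner_drug,
    n_articles = nrow(subset), min_weight = as.integer(min_weight)
  ))
}

node_colors <- c(drug = "red", protein = "blue", phenomena = "green",
                 interaction = "orange")

as_igraph_network <- function(network) {
  vertices <- mutate(network$nodes,
                     category = .data$category,
                     color_group = unname(node_colors[.data$category]))
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = vertices)
  for (f in names(network$provenance)) {
    v <- network$provenance[[f]]
    if (!is.null(v)) g <- igraph::set_graph_attr(g, f, v)
  }
  g
}

#' Export / import a term network
#'
#' GraphML carries node attributes `category` and `color_group`, the edge
#' attribute `weight`, and the provenance fields as graph attributes, so
#' re-import reproduces the network. The TSV format is a plain edge list
#' (`source`, `target`, `weight`); a companion `<path>.nodes.tsv` carries
#' (`term`, `category`).
#'
#' @param network A `ddi_network`.
#' @param path File path.
#' @param format `"graphml"` or `"tsv"`.
#' @return `read_term_network()` returns the `ddi_network`.
#' @export
write_term_network <- function(network, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph_network(network), path, format = "graphml")
  } else {
    readr::write_tsv(rename(network$edges, source = "from", target = "to"),
                     path, progress = FALSE)
    readr::write_tsv(network$nodes, paste0(path, ".nodes.tsv"), progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_term_network
#' @export
read_term_network <- function(path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- tibble(term = igraph::V(g)$name, category = igraph::V(g)$category)
    el <- igraph::as_data_frame(g, what = "edges")
    edges <- tibble(from = el$from, to = el$to,
                    weight = as.integer(round(el$weight))) %>%
      arrange(.data$from, .data$to)
    prov <- lapply(setNames(nm = igraph::graph_attr_names(g)),
                   function(a) igraph::graph_attr(g, a))
    if (!is.null(prov$n_articles)) prov$n_articles <- as.integer(prov$n_articles)
    if (!is.null(prov$min_weight)) prov$min_weight <- as.integer(prov$min_weight)
  } else {
    el <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    edges <- tibble(from = el$source, to = el$target,
                    weight = as.integer(el$weight)) %>%
      arrange(.data$from, .data$to)
    nodes <- readr::read_tsv(paste0(path, ".nodes.tsv"), show_col_types = FALSE,
                             progress = FALSE)
    prov <- list()
  }
  new_ddi_network(as_tibble(nodes), edges, prov)
}

#' @export
autoplot.ddi_network <- function(object, ...) {
  g <- as_igraph_network(object)
  lay <- igraph::layout_with_fr(g)
  df <- tibble(x = lay[, 1L], y = lay[, 2L],
               term = igraph::V(g)$name, category = igraph::V(g)$category)
  ed <- object$edges %>%
    left_join(df, by = c(from = "term")) %>%
    rename(x0 = "x", y0 = "y") %>%
    left_join(df, by = c(to = "term"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x, yend = .data$y,
                                       linewidth = .data$weight),
                          colour = "grey70") +
    ggplot2::geom_point(data = df,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$category), size = 3) +
    ggplot2::geom_text(data = df,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$term),
                       vjust = -1, size = 3) +
    ggplot2::scale_colour_manual(values = node_colors) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::theme_void()
}
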