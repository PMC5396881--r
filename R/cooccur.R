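# Term-article incidence, term-term adjacency, row normalization for
# heatmaps, and hierarchical-clustering leaf orders.

#' Term-article incidence matrix
#'
#' Binary matrix with one row per article and one column per term; entry
#' (b, a) is 1 iff term a appears among article b's qualifier-stripped
#' descriptors.
#'
#' @param articles Article tibble.
#' @param terms Character vector of descriptors (unique).
#' @return Integer 0/1 matrix with pmids as row names, terms as column
#'   names.
#' @export
build_incidence <- function(articles, terms) {
  if (anyDuplicated(norm_term(terms))) {
    stop("duplicate term in term list: ", terms[duplicated(norm_term(terms))][1L])
  }
  key <- norm_term(terms)
  desc <- article_descriptors(articles)
  m <- matrix(0L, nrow = nrow(articles), ncol = length(terms),
              dimnames = list(articles$pmid, terms))
  for (i in seq_along(desc)) {
    m[i, ] <- as.integer(key %in% norm_term(desc[[i]]))
  }
  m
}

#' Term-term adjacency from an incidence matrix
#'
#' `t(incidence) %*% incidence`: entry (i, j) is the number of articles
#' containing both term i and term j; the diagonal is each term's document
#' frequency. Exact integer arithmetic.
#'
#' @param incidence 0/1 matrix from [build_incidence()].
#' @return Symmetric integer matrix (terms x terms).
#' @export
build_adjacency <- function(incidence) {
  stopifnot(all(incidence %in% c(0L, 1L)))
  a <- crossprod(incidence)
  storage.mode(a) <- "integer"
  a
}

#' Row-normalize a count matrix
#'
#' Divides each entry by its row total (the heatmap normalization:
#' normalized count = count / total row count), so every nonzero row sums
#' to 1. All-zero rows are left at zero and reported with a message.
#'
#' @param counts Non-negative matrix.
#' @return Real matrix with entries in \[0, 1\].
#' @export
normalize_rows <- function(counts) {
  stopifnot(all(counts >= 0))
  rs <- rowSums(counts)
  zero <- rs == 0
  if (any(zero)) {
    message(sum(zero), " all-zero row(s) left unnormalized")
    rs[zero] <- 1
  }
  counts / rs
}

#' Cross co-occurrence counts between two term sets
#'
#' Entry (i, j) is the number of articles containing both `row_terms[i]`
#' and `col_terms[j]`. In pipeline use the rows are selected drug terms and
#' the columns selected protein (or phenomena) terms, restricted to group A
#' articles; a term appearing in both lists has its document frequency on
#' the corresponding cell.
#'
#' @param articles Article tibble.
#' @param row_terms,col_terms Unique descriptor vectors (may overlap each
#'   other).
#' @return Integer count matrix (row_terms x col_terms).
#' @export
cross_cooccurrence <- function(articles, row_terms, col_terms) {
  m <- crossprod(build_incidence(articles, row_terms),
                 build_incidence(articles, col_terms))
  storage.mode(m) <- "integer"
  m
}

#' Dendrogram leaf orders for heatmap display
#'
#' Agglomerative hierarchical clustering on Euclidean distances between row
#' vectors and, independently, column vectors; returns the leaf orders used
#' to arrange heatmap axes. With fewer than two rows (or columns) the
#' identity permutation is returned.
#'
#' @param m Finite numeric matrix.
#' @param method Linkage: `"complete"` (default), `"single"`, or
#'   `"average"`.
#' @return List with integer permutations `rows` and `cols`.
#' @export
cluster_order <- function(m, method = c("complete", "single", "average")) {
  method <- match.arg(method)
  stopifnot(all(is.finite(m)))
  leaf_order <- function(x) {
    if (nrow(x) < 2L) seq_len(nrow(x)) else hclust(dist(x), method = method)$order
  }
  list(rows = leaf_order(m), cols = leaf_order(t(m)))
}

#' Co-occurrence model for a term set
#'
#' Bundles the incidence matrix, the adjacency (`t(I) %*% I`), the
#' row-normalized adjacency, and the clustering orders of the normalized
#' matrix.
#'
#' @param articles Article tibble.
#' @param terms Unique descriptor vector.
#' @param method Linkage passed to [cluster_order()].
#' @return Object of class `cooccurrence_model`.
#' @export
cooccurrence_model <- function(articles, terms, method = "complete") {
  inc <- build_incidence(articles, terms)
  adj <- build_adjacency(inc)
  norm <- suppressMessages(normalize_rows(adj))
  structure(
    list(
      terms = terms, pmids = articles$pmid,
      incidence = inc, adjacency = adj, row_normalized = norm,
      order = cluster_order(norm, method = method)
    ),
    class = "cooccurrence_model"
  )
}

#' @export
print.cooccurrence_model <- function(x, ...) {
  cat(sprintf("<cooccurrence_model> %d terms x %d articles\n",
              length(x$terms), length(x$pmids)))
  invisible(x)
}

#' @export
autoplot.cooccurrence_model <- function(object, ...) {
  plot_cooccurrence(object$row_normalized, order = object$order)
}

#' Heatmap of a (normalized) co-occurrence matrix
#'
#' ggplot2 tile heatmap with axes arranged by the supplied clustering
#' orders (computed with [cluster_order()] when omitted).
#'
#' @param m Numeric matrix with dimnames.
#' @param order Optional list of `rows`/`cols` permutations.
#' @param fill_name Legend title.
#' @return A ggplot object.
#' @export
plot_cooccurrence <- function(m, order = NULL, fill_name = "normalized count") {
  if (is.null(order)) order <- cluster_order(m)
  m <- m[order$rows, order$cols, drop = FALSE]
  df <- as_tibble(as.table(m), .name_repair = ~ c("row", "col", "value"))
  df$row <- factor(df$row, levels = rownames(m))
  df$col <- factor(df$col, levels = colnames(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 name = fill_name) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1, vjust = 0.5))
}

#' Write / read a named matrix as TSV
#'
#' Header row and first column carry term names; an optional
#' `# config_hash:` comment line precedes the header.
#'
#' @param m Matrix with dimnames.
#' @param path File path.
#' @param hash Optional configuration hash for the header comment.
#' @return `read_matrix_tsv()` returns the matrix.
#' @export
write_matrix_tsv <- function(m, path, hash = NULL) {
  df <- bind_cols(tibble(term = rownames(m)), as_tibble(m))
  if (!is.null(hash)) {
    writeLines(sprintf("# config_hash: %s", hash), path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  } else {
    readr::write_tsv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
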