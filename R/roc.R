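# ROC validation of ranked candidate terms against gold-standard labels.

#' ROC curve for a labeled ranking
#'
#' Sensitivity against one minus specificity across all distinct score
#' thresholds, with the endpoints (0, 0) and (1, 1). Tied scores move
#' together (the Mann-Whitney tie convention), producing diagonal segments;
#' this makes the trapezoidal area identical to the pairwise Mann-Whitney
#' statistic.
#'
#' @param scores Numeric ranking scores (by default p-values, so smaller
#'   ranks higher).
#' @param labels 0/1 gold-standard labels; both classes must be present.
#' @param smaller_is_better `TRUE` (default) when smaller scores rank
#'   higher.
#' @return Tibble with columns `threshold` (`NA` for the (0,0) endpoint),
#'   `fpr`, `tpr`, ordered along the curve.
#' @export
roc_curve <- function(scores, labels, smaller_is_better = TRUE) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (all(labels == 1)) stop("all labels are positive; specificity undefined")
  if (all(labels == 0)) stop("all labels are negative; sensitivity undefined")
  s <- if (smaller_is_better) -as.numeric(scores) else as.numeric(scores)
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]
  lab <- labels[ord]
  last <- !duplicated(s, fromLast = TRUE)   # end of each tie block
  tp <- cumsum(lab)[last]
  fp <- cumsum(1 - lab)[last]
  tibble(
    threshold = c(NA_real_, scores[ord][last]),
    fpr = c(0, fp / sum(labels == 0)),
    tpr = c(0, tp / sum(labels == 1))
  )
}

#' Area under a ROC curve
#'
#' Trapezoidal area over the points of [roc_curve()]; equal (to machine
#' precision) to the probability that a random positive outranks a random
#' negative, counting ties one half.
#'
#' @param points Tibble of `fpr`, `tpr` sorted along the curve, or the
#'   result of [roc_curve()].
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(points) {
  fpr <- points$fpr
  tpr <- points$tpr
  sum(diff(fpr) * (head(tpr, -1L) + tpr[-1L]) / 2)
}

#' AUC sweep over the frequency cutoff
#'
#' Re-evaluates the ROC on the terms surviving each group-A frequency
#' cutoff (`count_a > cutoff`), tracing how the count filter trades
#' candidate coverage against ranking quality. A cutoff whose restriction
#' loses one label class entirely is reported with `NA` AUC and the sweep
#' continues.
#'
#' @param ranking Tibble with columns `count_a`, `score` (p-value) and
#'   `label` (0/1); e.g. `tidy(enrichment)` joined to gold labels.
#' @param cutoffs Integer vector of frequency cutoffs (default 0:6).
#' @param smaller_is_better Passed to [roc_curve()].
#' @return Tibble: `cutoff`, `n_terms`, `n_pos`, `n_neg`, `auc`, and a
#'   `roc` list-column of ROC point tibbles (`NULL` where undefined).
#' @export
cutoff_sweep <- function(ranking, cutoffs = 0:6, smaller_is_better = TRUE) {
  stopifnot(all(c("count_a", "score", "label") %in% names(ranking)))
  rows <- lapply(cutoffs, function(ct) {
    sub <- filter(ranking, .data$count_a > ct)
    defined <- nrow(sub) > 0L && length(unique(sub$label)) == 2L
    pts <- if (defined) {
      roc_curve(sub$score, sub$label, smaller_is_better = smaller_is_better)
    }
    tibble(
      cutoff = ct, n_terms = nrow(sub),
      n_pos = sum(sub$label == 1), n_neg = sum(sub$label == 0),
      auc = if (defined) roc_auc(pts) else NA_real_,
      roc = list(pts)
    )
  })
  bind_rows(rows)
}

#' Read a gold-standard label file
#'
#' Two-column TSV `term<TAB>label` with labels 0/1 (1 = the identified
#' term is a true DDI partner or mechanism protein).
#'
#' @param path File path.
#' @return Tibble (`term`, `label`).
#' @export
read_gold_labels <- function(path) {
  df <- readr::read_tsv(path, col_types = "ci", progress = FALSE)
  names(df)[1:2] <- c("term", "label")
  stopifnot(all(df$label %in% c(0L, 1L)))
  df
}

#' Plot one or more ROC curves
#'
#' @param curves A ROC point tibble, or a named list of them.
#' @return A ggplot object.
#' @export
plot_roc <- function(curves) {
  if (is.data.frame(curves)) curves <- list(ROC = curves)
  df <- bind_rows(lapply(curves, function(x) x[c("fpr", "tpr")]), .id = "curve")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$curve)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity")
}
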