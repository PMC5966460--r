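#' Hierarchical clustering with Pearson correlation distance
#'
#' Agglomerative clustering with distance `1 - Pearson correlation` and
#' complete linkage, the combination used for expression-signature heatmaps.
#' By default the columns (samples) of the matrix are clustered; set
#' `margin = "rows"` to cluster features. Note that matrices mixing baseline
#' and post-gel samples should contain abundances that are *not*
#' baseline-normalized, otherwise the baseline columns are artificially
#' compressed.
#'
#' @param x Numeric matrix (features in rows, samples in columns), or a long
#'   tibble with a feature id column, `sample_id` and a single value column.
#' @param margin `"columns"` (default) or `"rows"`.
#' @return Object of class `feature_clustering`: a list with the
#'   [stats::hclust()] tree (`hclust`), the leaf `order`, `labels`, and
#'   `merge_heights`.
#' @examples
#' m <- matrix(rnorm(40), nrow = 10,
#'             dimnames = list(paste0("f", 1:10), paste0("s", 1:4)))
#' cl <- hierarchical_cluster(m)
#' cl$labels[cl$order]
#' @export
hierarchical_cluster <- function(x, margin = c("columns", "rows")) {
  margin <- match.arg(margin)
  mat <- as_feature_matrix(x)
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    abort("need at least 2 rows and 2 columns to cluster")
  }
  series <- if (margin == "columns") t(mat) else mat
  sds <- apply(series, 1, sd)
  if (any(sds == 0)) {
    abort(sprintf("constant %s (Pearson correlation undefined): %s",
                  if (margin == "columns") "column(s)" else "row(s)",
                  toString(rownames(series)[sds == 0])))
  }
  d <- as.dist(1 - cor(t(series)))
  tree <- hclust(d, method = "complete")
  structure(list(
    hclust = tree,
    order = tree$order,
    labels = tree$labels,
    merge_heights = tree$height,
    margin = margin
  ), class = "feature_clustering")
}

as_feature_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) {
    feature <- intersect(c("protein_id", "taxon_id", "feature_id"), names(x))
    value <- setdiff(names(x), c(feature, "sample_id"))
    if (length(feature) != 1 || length(value) != 1) {
      abort("long input needs one feature id column, sample_id, and one value column")
    }
    wide <- tidyr::pivot_wider(x, names_from = "sample_id",
                               values_from = dplyr::all_of(value))
    mat <- as.matrix(wide[, -1])
    rownames(mat) <- wide[[1]]
    return(mat)
  }
  abort("`x` must be a matrix or a long data frame")
}

#' Export a clustering as a Newick tree
#'
#' @param clustering A `feature_clustering` from [hierarchical_cluster()].
#' @param file Optional path; when given the tree is written there.
#' @return The Newick string, invisibly when written to a file.
#' @export
as_newick <- function(clustering, file = NULL) {
  stopifnot(inherits(clustering, "feature_clustering"))
  phy <- ape::as.phylo(clustering$hclust)
  if (is.null(file)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = file)
    invisible(ape::write.tree(phy))
  }
}

#' @export
print.feature_clustering <- function(x, ...) {
  cat(sprintf("<feature_clustering: %d leaves (%s), complete linkage, 1 - Pearson r>\n",
              length(x$labels), x$margin))
  invisible(x)
}
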