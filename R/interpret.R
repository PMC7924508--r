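#' Attainable value sets of each encoded feature
#'
#' The perturbation domain of a feature is the finite set of values it can
#' take in the encoded space: \{0,1\} for indicators, the sorted distinct
#' observed values for normalized numerics. Numeric domains with more than
#' `max_values` distinct values are capped by quantile-based representatives
#' so the perturbation sweep stays finite.
#'
#' @param features A preprocessed `feature_table` (or cohort/matrix).
#' @param max_values Cap on representatives per feature (default 25).
#' @return Named list of numeric vectors, one per feature.
#' @export
feature_domains <- function(features, max_values = 25) {
  X <- resolve_features(features)
  out <- lapply(seq_len(ncol(X)), function(j) {
    v <- sort(unique(X[, j]))
    if (length(v) > max_values) {
      v <- sort(unique(unname(quantile(X[, j], probs = seq(0, 1, length.out = max_values)))))
    }
    v
  })
  names(out) <- colnames(X)
  out
}

#' Maximal perturbation impact of each feature on the embedding
#'
#' For every record, every feature and every alternative value in the
#' feature's domain, the record is re-encoded with that single substitution
#' and the absolute change of each embedding unit recorded. The primary
#' aggregation is the maximum over records and alternatives ("maximum
#' impact"); the mean is also kept as a secondary summary. A feature the
#' encoder ignores (all-zero weights) gets an all-zero row.
#'
#' @param model A `trained_embedder`.
#' @param features Preprocessed features compatible with the model.
#' @param domains Optional [feature_domains()]; computed from `features`
#'   otherwise.
#' @return An `impact_matrix`: list with `max` and `mean` (`d x m` matrices),
#'   `feature_names`.
#' @export
feature_impact <- function(model, features, domains = NULL) {
  X <- resolve_features(features)
  domains <- domains %||% feature_domains(X)
  if (any(lengths(domains) == 0)) {
    abort(paste0("Empty perturbation domain for feature '",
                 names(domains)[which(lengths(domains) == 0)[1]], "'."))
  }
  E0 <- embed_cohort(model, X)
  d <- ncol(X); m <- ncol(E0)
  imp_max <- matrix(0, d, m, dimnames = list(colnames(X), colnames(E0)))
  imp_mean <- imp_max
  for (j in seq_len(d)) {
    acc_n <- 0
    for (v in domains[[j]]) {
      rows <- which(X[, j] != v)
      if (length(rows) == 0) next
      Xp <- X[rows, , drop = FALSE]
      Xp[, j] <- v
      delta <- abs(embed_cohort(model, Xp) - E0[rows, , drop = FALSE])
      imp_max[j, ] <- pmax(imp_max[j, ], apply(delta, 2, max))
      imp_mean[j, ] <- imp_mean[j, ] + colSums(delta)
      acc_n <- acc_n + length(rows)
    }
    if (acc_n > 0) imp_mean[j, ] <- imp_mean[j, ] / acc_n
  }
  structure(list(max = imp_max, mean = imp_mean,
                 feature_names = colnames(X)),
            class = "impact_matrix")
}

#' @export
print.impact_matrix <- function(x, ...) {
  cat("<impact_matrix> ", nrow(x$max), " features x ", ncol(x$max),
      " embedding units; top feature: ",
      rownames(x$max)[which.max(apply(x$max, 1, max))], "\n", sep = "")
  invisible(x)
}

#' Agglomerative clustering of features by embedding impact
#'
#' Hierarchically clusters the rows of the impact matrix so features with a
#' similar effect on the embedding group together (e.g. risk behaviours the
#' model treats interchangeably). Euclidean distance with average linkage by
#' default.
#'
#' @param impact An `impact_matrix` (its `max` aggregation is clustered).
#' @param linkage `stats::hclust` method (default `"average"`).
#' @param metric `stats::dist` method (default `"euclidean"`).
#' @param k Number of flat clusters to cut (default `min(4, d - 1)`).
#' @return A `feature_clustering`: list with `tree` (hclust), `assignment`
#'   (named cluster ids at the cut), `linkage`, `metric`.
#' @export
cluster_features <- function(impact, linkage = "average",
                             metric = "euclidean", k = NULL) {
  M <- impact$max
  if (nrow(M) < 2) abort("Need at least two features to cluster.")
  if (!all(is.finite(M))) abort("Impact matrix has non-finite entries.")
  tree <- hclust(dist(M, method = metric), method = linkage)
  k <- k %||% min(4L, nrow(M) - 1L)
  structure(list(tree = tree, assignment = cutree(tree, k = k),
                 linkage = linkage, metric = metric, k = k),
            class = "feature_clustering")
}

#' @export
print.feature_clustering <- function(x, ...) {
  cat("<feature_clustering> ", length(x$tree$labels), " features, ",
      x$linkage, " linkage, ", x$metric, " distance; ", x$k,
      " flat clusters\n", sep = "")
  invisible(x)
}

#' Export a feature dendrogram in Newick format
#'
#' Leaf names are the feature names; branch lengths derive from the merge
#' heights.
#'
#' @param clustering A [cluster_features()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_clustering_newick <- function(clustering, path) {
  phy <- ape::as.phylo(clustering$tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Project embeddings to two dimensions for visualization
#'
#' Projects the learned embedding to 2-D with principal components
#' (`"pca"`) or classical multidimensional scaling (`"mds"`) and returns the
#' coordinates with class labels ready for plotting. Deterministic; the seed
#' argument pins any future stochastic backend.
#'
#' @param model A `trained_embedder`.
#' @param cohort A `labeled_cohort` with preprocessed features.
#' @param method `"pca"` or `"mds"`.
#' @param seed Integer seed.
#' @return An `embedding_projection` tibble: `dim1`, `dim2`, `label`.
#' @export
project_embeddings <- function(model, cohort, method = c("pca", "mds"),
                               seed = 1L) {
  method <- match.arg(method)
  if (cohort$features$n < 10) abort("Need at least 10 records to project.")
  E <- embed_cohort(model, cohort)
  coords <- withr::with_seed(seed, {
    if (method == "pca") {
      p <- prcomp(E, center = TRUE, scale. = FALSE)
      cbind(p$x[, 1], if (ncol(p$x) > 1) p$x[, 2] else 0)
    } else {
      cmdscale(dist(E), k = 2)
    }
  })
  out <- tibble::tibble(dim1 = coords[, 1], dim2 = coords[, 2],
                        label = cohort$labels)
  class(out) <- c("embedding_projection", class(out))
  out
}

#' Write an impact matrix as TSV (features x embedding units)
#'
#' @param impact An `impact_matrix`.
#' @param path Output file.
#' @param which `"max"` (primary) or `"mean"` aggregation.
#' @return `path`, invisibly.
#' @export
write_impact_tsv <- function(impact, path, which = c("max", "mean")) {
  which <- match.arg(which)
  M <- impact[[which]]
  df <- tibble::as_tibble(as.data.frame(M, check.names = FALSE))
  df <- dplyr::mutate(df, feature = rownames(M), .before = 1)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
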