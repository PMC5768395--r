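# Two-way unsupervised hierarchical clustering of samples x sites on
# log10-transformed methylation, average linkage, with a two-cluster cut of
# the sample tree and a composition/purity summary.

#' Two-way average-linkage clustering
#'
#' Values are transformed as log10((v + pseudocount) / pseudocount), i.e. the
#' decadic log referenced to the detection floor: monotone in v, zero-safe,
#' and non-negative so that Bray-Curtis dissimilarity is well defined (for
#' Euclidean distances the reference shift is immaterial). Samples and sites
#' are clustered by average linkage (UPGMA) on their respective distance
#' matrices and the sample tree is cut at its top merge into two clusters;
#' the cluster holding the majority of normal samples is labelled `N-like`.
#'
#' @param x a site-level [MethylationExperiment-class] with >= 3 samples.
#' @param distance `"bray"` (Bray-Curtis, the vegan default) or
#'   `"euclidean"`.
#' @param linkage agglomeration method (default `"average"`).
#' @param pseudocount added before the log; default 0.005, half the 1%
#'   detection floor of the dilution standard curve.
#' @return object of class `ClusterResult`: list with `sample_tree`,
#'   `site_tree` (hclust objects), `labels` (named, `"N-like"`/`"T-like"`),
#'   `composition` (class x cluster counts), `misassigned`, and the
#'   parameters used.
#' @export
clusterTwoWay <- function(x, distance = c("bray", "euclidean"),
                          linkage = "average", pseudocount = 0.005) {
  stopifnot(is(x, "MethylationExperiment"))
  distance <- match.arg(distance)
  if (ncol(x) < 3) .msErr("data", "need at least 3 samples to cluster")
  v <- methValues(x)
  if (any(v < 0, na.rm = TRUE)) .msErr("range", "negative methylation values")
  tr <- log10((v + pseudocount) / pseudocount)  # sites x samples
  distFun <- function(m) {
    if (distance == "bray") vegan::vegdist(m, method = "bray", na.rm = TRUE)
    else stats::dist(m)
  }
  sample_tree <- stats::hclust(distFun(t(tr)), method = linkage)
  site_tree <- if (nrow(x) >= 3)
    stats::hclust(distFun(tr), method = linkage) else NULL
  cut2 <- stats::cutree(sample_tree, k = 2)
  cls <- sampleClass(x)
  n_normals <- vapply(1:2, function(g) sum(cls[cut2 == g] == "normal"),
                      numeric(1))
  n_like <- which.max(n_normals)  # ties resolve to cluster 1
  labels <- ifelse(cut2 == n_like, "N-like", "T-like")
  names(labels) <- colnames(x)
  composition <- table(class = cls, cluster = labels)
  mis <- sum(cls == "tumor" & labels == "N-like") +
    sum(cls == "normal" & labels == "T-like")
  structure(list(sample_tree = sample_tree, site_tree = site_tree,
                 labels = labels, composition = composition,
                 misassigned = mis, stage = sampleStage(x), class = cls,
                 distance = distance, linkage = linkage,
                 pseudocount = pseudocount),
            class = "ClusterResult")
}

#' Cluster composition and misassignment
#'
#' Per-cluster counts by class and stage; a sample is misassigned when its
#' class is the minority class of its cluster's label (tumors in `N-like`,
#' normals in `T-like`).
#'
#' @param result a [clusterTwoWay()] result.
#' @return list with `composition` (data.frame: cluster, class, stage, n) and
#'   `misassigned` (count).
#' @export
clusterPurity <- function(result) {
  stopifnot(inherits(result, "ClusterResult"))
  df <- as.data.frame(table(cluster = result$labels, class = result$class,
                            stage = result$stage))
  df <- df[df$Freq > 0, ]
  names(df)[names(df) == "Freq"] <- "n"
  rownames(df) <- NULL
  list(composition = df, misassigned = result$misassigned)
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat(sprintf("Two-way %s-linkage clustering (%s distance, pseudocount %g)\n",
              x$linkage, x$distance, x$pseudocount))
  print(x$composition)
  cat(sprintf("misassigned samples at the two-cluster cut: %d\n", x$misassigned))
  invisible(x)
}

#' Heatmap of the clustered matrix (inspection only)
#'
#' Draws the log-transformed site x sample matrix with the trees from
#' [clusterTwoWay()], via pheatmap when available.
#'
#' @param x the [MethylationExperiment-class] that was clustered.
#' @param result the matching [clusterTwoWay()] result.
#' @param ... passed to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
plotClusterHeatmap <- function(x, result, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    .msErr("config", "plotClusterHeatmap requires the pheatmap package")
  tr <- log10((methValues(x) + result$pseudocount) / result$pseudocount)
  ann <- data.frame(class = sampleClass(x), row.names = colnames(x))
  invisible(pheatmap::pheatmap(
    tr, cluster_rows = result$site_tree, cluster_cols = result$sample_tree,
    annotation_col = ann, ...))
}
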