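#' Collapse replicate columns to per-compound mean signatures
#'
#' @param m an [expression_matrix()].
#' @param include_controls keep control columns (as compound "control")?
#' @return proteins x compounds numeric matrix of replicate-mean log2 fold
#'   changes.
#' @export
compound_signatures <- function(m, include_controls = FALSE) {
  stopifnot(inherits(m, "expression_matrix"))
  d <- m$design
  keep <- if (include_controls) rep(TRUE, nrow(d)) else !d$is_control
  comps <- unique(d$compound[keep])
  sig <- vapply(comps, function(cc) {
    rowMeans(m$values[, keep & d$compound == cc, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(m$values)))
  rownames(sig) <- rownames(m$values)
  sig
}

.cor_dist <- function(x) {
  # 1 - Pearson correlation between columns of x
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant signature(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  stats::as.dist(1 - stats::cor(x))
}

.hier_cluster <- function(mat_items_in_cols, distance, linkage, k) {
  dd <- switch(distance,
               pearson = .cor_dist(mat_items_in_cols),
               euclidean = stats::dist(t(mat_items_in_cols)))
  hc <- stats::hclust(dd, method = linkage)
  flat <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  structure(list(tree = hc, flat_clusters = flat, distance = distance,
                 linkage_method = linkage),
            class = "cluster_result")
}

#' Hierarchical clustering of compound signatures
#'
#' Replicates are collapsed to per-compound mean signatures, compounds are
#' compared by 1 - Pearson correlation and clustered hierarchically.
#' Compounds sharing targets or a mechanism of action aggregate into
#' clusters.
#'
#' @param m an [expression_matrix()].
#' @param distance `"pearson"` (1 - r, default) or `"euclidean"`.
#' @param linkage agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param k optional number of flat clusters to cut.
#' @return Object of class `cluster_result`: `tree` (an `hclust`),
#'   `flat_clusters` (or `NULL`), `distance`, `linkage_method`.
#' @export
cluster_compounds <- function(m, distance = c("pearson", "euclidean"),
                              linkage = "average", k = NULL) {
  distance <- match.arg(distance)
  sig <- compound_signatures(m)
  if (anyNA(sig)) {
    stop("signatures contain missing values; merge with policy = \"complete\"")
  }
  .hier_cluster(sig, distance, linkage, k)
}

#' Hierarchical clustering of proteins into co-regulation modules
#'
#' Proteins are compared by the 1 - Pearson correlation of their
#' per-compound mean profiles and cut into `k` flat clusters.
#'
#' @inheritParams cluster_compounds
#' @param k number of protein clusters (default 15).
#' @return A `cluster_result` with `flat_clusters` labeling every protein.
#' @export
cluster_proteins <- function(m, k = 15L, distance = c("pearson", "euclidean"),
                             linkage = "average") {
  distance <- match.arg(distance)
  sig <- compound_signatures(m)
  if (anyNA(sig)) {
    stop("signatures contain missing values; merge with policy = \"complete\"")
  }
  .hier_cluster(t(sig), distance, linkage, k)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", length(x$tree$order), "items,",
      x$distance, "distance,", x$linkage_method, "linkage")
  if (!is.null(x$flat_clusters)) {
    cat(",", length(unique(x$flat_clusters)), "flat clusters")
  }
  cat("\n")
  invisible(x)
}

#' Count informative principal dimensions of the signature space
#'
#' Runs PCA on the per-compound mean signatures (compounds as
#' observations) and counts the components whose variance fraction is at
#' least `min_var_frac`.
#'
#' @param m an [expression_matrix()].
#' @param min_var_frac minimum variance fraction (default 0.01, i.e. 1%).
#' @param excluded_compounds compounds dropped before the PCA (gross
#'   outliers dominate the leading components if kept).
#' @return List with `n_dims` and `var_frac` (fractions summing to 1).
#' @export
pca_screen <- function(m, min_var_frac = 0.01,
                       excluded_compounds = character(0)) {
  sig <- compound_signatures(m)
  sig <- sig[, !(colnames(sig) %in% excluded_compounds), drop = FALSE]
  if (anyNA(sig)) {
    stop("signatures contain missing values; merge with policy = \"complete\"")
  }
  pc <- stats::prcomp(t(sig), center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(n_dims = sum(vf >= min_var_frac), var_frac = vf)
}

#' Mean regulation of each protein cluster under a compound group
#'
#' The per-cluster engagement values are what a radar plot of cluster
#' regulation displays: the mean, over the cluster's proteins, of the
#' replicate-mean log2 fold change averaged over the compounds in the
#' group.
#'
#' @param m an [expression_matrix()].
#' @param protein_clusters a `cluster_result` from [cluster_proteins()] or
#'   a named cluster-label vector over the matrix's proteins.
#' @param compound_group character vector of compounds.
#' @return Named numeric vector: mean log2 fold change per cluster.
#' @export
cluster_engagement <- function(m, protein_clusters, compound_group) {
  stopifnot(inherits(m, "expression_matrix"))
  labels <- if (inherits(protein_clusters, "cluster_result")) {
    protein_clusters$flat_clusters
  } else protein_clusters
  labels <- labels[rownames(m$values)]
  if (anyNA(labels)) stop("cluster labels do not cover all proteins")
  sig <- compound_signatures(m)
  missing_comp <- setdiff(compound_group, colnames(sig))
  if (length(missing_comp) > 0L) {
    stop("compound(s) not in the matrix: ",
         paste(missing_comp, collapse = ", "))
  }
  prof <- rowMeans(sig[, compound_group, drop = FALSE], na.rm = TRUE)
  out <- tapply(prof, labels, mean, na.rm = TRUE)
  stats::setNames(as.numeric(out), names(out))
}

#' Export a dendrogram in Newick format
#'
#' @param cr a `cluster_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_newick <- function(cr, path) {
  stopifnot(inherits(cr, "cluster_result"))
  ape::write.tree(ape::as.phylo(cr$tree), file = path)
  invisible(path)
}
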