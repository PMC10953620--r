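#' Calinski-Harabasz index of a partition
#'
#' Ratio of between-cluster to within-cluster dispersion, normalized by
#' degrees of freedom: `[B/(k-1)] / [W/(n-k)]` with B and W the between- and
#' within-cluster sums of squared Euclidean distances to centroids. Larger
#' is better-separated. A partition with zero within-cluster dispersion
#' returns `Inf` (perfect-separation sentinel).
#'
#' @param x numeric matrix (observations x features) or vector.
#' @param labels cluster labels, one per row of `x`, with k >= 2 nonempty
#'   clusters and k < n.
#' @return the index (possibly `Inf`).
#' @examples
#' calinski_harabasz(c(0, 2, 10, 12), c("A", "A", "B", "B"))  # 50
#' @export
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  n <- nrow(x)
  k <- length(unique(labels))
  if (k < 2) stop_ac("need at least 2 clusters")
  if (k >= n) stop_ac("every cluster is a singleton (k = n); index undefined")
  grand <- colMeans(x)
  W <- 0
  B <- 0
  for (g in unique(labels)) {
    xg <- x[labels == g, , drop = FALSE]
    cg <- colMeans(xg)
    W <- W + sum(sweep(xg, 2, cg)^2)
    B <- B + nrow(xg) * sum((cg - grand)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Ward hierarchical clustering with Calinski-Harabasz model selection
#'
#' Builds the agglomerative Ward tree (Ward's minimum-variance criterion on
#' Euclidean distances over all feature dimensions), evaluates the
#' Calinski-Harabasz index at every candidate number of clusters, and cuts
#' the tree at the maximizing k. Subtype ids are assigned by descending
#' cluster size (subtype 1 = largest; ties broken by smallest subject id).
#'
#' @param z_rates numeric matrix, subjects x features (standardized atrophy
#'   rates); must have no missing entries and row names identifying
#'   subjects. Columns that are entirely `NA` (non-converged ROIs) are
#'   dropped with a message.
#' @param k_range candidate cluster numbers, within `[2, n-1]`.
#' @param k fix the number of clusters instead of selecting by the index
#'   (used when reclustering resamples at the reference k).
#' @return object of class `cluster_solution`: `labels` (named integer
#'   vector of subtype ids), `k`, `ch_profile` (tibble k, ch), `hclust` (the
#'   tree), `merge_table` (tibble of merges and heights).
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 8), ncol = 2))
#' rownames(x) <- paste0("s", 1:30)
#' sol <- ward_cluster(x)
#' sol$k
#' @export
ward_cluster <- function(z_rates, k_range = 2:10, k = NULL) {
  z <- as.matrix(z_rates)
  if (is.null(rownames(z))) rownames(z) <- sprintf("obs_%03d", seq_len(nrow(z)))
  all_na <- colSums(!is.na(z)) == 0
  if (any(all_na)) {
    message(sum(all_na), " all-missing feature columns dropped")
    z <- z[, !all_na, drop = FALSE]
  }
  if (anyNA(z)) stop_ac("z_rates contains missing entries")
  n <- nrow(z)
  if (!is.null(k)) k_range <- k
  if (min(k_range) < 2 || max(k_range) > n - 1) {
    stop_ac("k_range must lie within [2, n-1]")
  }

  total_ss <- sum(sweep(z, 2, colMeans(z))^2)
  if (total_ss == 0) {
    stop_ac("all observations identical: zero total dispersion, clustering undefined")
  }

  hc <- hclust(dist(z), method = "ward.D2")
  ch <- vapply(k_range, function(kk) {
    calinski_harabasz(z, cutree(hc, k = kk))
  }, numeric(1))
  k_best <- if (!is.null(k)) k else k_range[which.max(ch)]
  raw_labels <- cutree(hc, k = k_best)
  labels <- relabel_by_size(raw_labels)

  structure(list(
    labels = labels,
    k = k_best,
    ch_profile = tibble::tibble(k = k_range, ch = ch),
    hclust = hc,
    merge_table = tibble::tibble(
      merge1 = hc$merge[, 1], merge2 = hc$merge[, 2], height = hc$height)),
    class = "cluster_solution")
}

# Relabel clusters 1..k by descending size; ties broken by the smallest
# member id (lexicographic), so subtype 1 is always the largest cluster.
relabel_by_size <- function(labels) {
  ids <- names(labels) %||% as.character(seq_along(labels))
  sizes <- table(labels)
  first_member <- tapply(ids, labels, min)
  ord <- order(-as.integer(sizes), first_member)
  new <- match(as.character(labels), names(sizes)[ord])
  setNames(as.integer(new), ids)
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("cluster_solution: k = %d, sizes %s (CH = %.2f)\n", x$k,
              paste(table(x$labels), collapse = "/"),
              max(x$ch_profile$ch)))
  invisible(x)
}

#' Cohen's kappa between two labelings
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)` after aligning the
#' second labeling to the first by the permutation maximizing the trace of
#' the confusion matrix (ties broken toward the identity).
#'
#' @param a,b label vectors of equal length (same subjects, same order), or
#'   `a` a k x k confusion matrix (then `b` is ignored).
#' @return list with `kappa`, `aligned` (the permutation applied to `b`'s
#'   label indices), and `table` (aligned confusion matrix).
#' @examples
#' cohen_kappa(matrix(c(20, 5, 5, 20), 2))$kappa  # 0.6
#' @export
cohen_kappa <- function(a, b = NULL) {
  if (is.matrix(a) && is.null(b)) {
    tab <- a
    perm <- seq_len(ncol(tab))
  } else {
    stopifnot(length(a) == length(b))
    a <- factor(a)
    b <- factor(b)
    kk <- max(nlevels(a), nlevels(b))
    tab0 <- table(factor(as.integer(a), levels = seq_len(kk)),
                  factor(as.integer(b), levels = seq_len(kk)))
    best <- -Inf
    perm <- seq_len(kk)
    for (p in perms(kk)) {
      tr <- sum(diag(tab0[, p, drop = FALSE]))
      if (tr > best + 1e-12) {
        best <- tr
        perm <- p
      }
    }
    tab <- tab0[, perm, drop = FALSE]
  }
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (pe == 1) 1 else (po - pe) / (1 - pe)
  list(kappa = kappa, aligned = perm, table = tab)
}

#' Validate a clustering against k-means on the first two principal
#' components
#'
#' Projects the standardized rate matrix onto its first two principal
#' components (centered, not re-scaled — the features are already
#' standardized), runs k-means with the reference solution's k (multiple
#' restarts under a fixed seed), aligns the k-means labels to the reference
#' by maximum-agreement permutation, and reports Cohen's kappa.
#'
#' @param z_rates subjects x features matrix used for the reference
#'   clustering.
#' @param reference a [ward_cluster()] solution on the same subjects.
#' @param seed integer seed for the k-means restarts.
#' @param nstart number of k-means restarts (best within-SS kept).
#' @return list with `kappa`, `table` (aligned confusion), `kmeans_labels`,
#'   `pc_scores` (subjects x 2).
#' @export
kmeans_pc_validation <- function(z_rates, reference, seed = 1L, nstart = 50) {
  stopifnot(inherits(reference, "cluster_solution"), reference$k >= 2)
  z <- as.matrix(z_rates)
  z <- z[, colSums(!is.na(z)) > 0, drop = FALSE]
  pc <- prcomp(z, center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1:2, drop = FALSE]
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)
  km <- kmeans(scores, centers = reference$k, nstart = nstart)
  km_labels <- relabel_by_size(setNames(km$cluster, rownames(z)))
  ref <- reference$labels[rownames(z) %||% names(reference$labels)]
  ck <- cohen_kappa(as.integer(ref), as.integer(km_labels))
  list(kappa = ck$kappa, table = ck$table,
       kmeans_labels = km_labels, pc_scores = scores)
}
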