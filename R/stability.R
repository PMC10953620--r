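#' Dice coefficient of two subject sets
#'
#' `2|A n B| / (|A| + |B|)`. Two empty sets are identically empty: the
#' coefficient is defined as 1 and flagged via the `"both_empty"` attribute.
#'
#' @param set_a,set_b vectors of subject ids (duplicates ignored).
#' @return the coefficient in `[0, 1]`.
#' @examples
#' dice(c(1, 2, 3), c(2, 3, 4))  # 2/3
#' @export
dice <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  if (!length(a) && !length(b)) {
    return(structure(1, both_empty = TRUE))
  }
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

# Match perturbed clusters to reference clusters by the label permutation
# maximizing total Dice overlap (equivalent to optimal assignment on the
# Dice-gain matrix; brute force over permutations, k <= 7). Returns the
# permutation p with perturbed cluster p[i] matched to reference cluster i,
# and the per-reference-cluster Dice.
match_clusters <- function(ref_sets, new_sets) {
  k <- length(ref_sets)
  stopifnot(length(new_sets) == k)
  dmat <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) dmat[i, j] <- dice(ref_sets[[i]], new_sets[[j]])
  }
  best <- -Inf
  best_p <- seq_len(k)
  for (p in perms(k)) {
    tot <- sum(dmat[cbind(seq_len(k), p)])
    if (tot > best + 1e-12) {
      best <- tot
      best_p <- p
    }
  }
  list(perm = best_p,
       dice = dmat[cbind(seq_len(k), best_p)],
       total = best)
}

# shared engine for jackknife and k-fold stability
stability_engine <- function(z, reference, drop_sets, scheme,
                             restrict_to_retained = TRUE) {
  z <- as.matrix(z)
  z <- z[, colSums(!is.na(z)) > 0, drop = FALSE]
  ids <- rownames(z)
  if (is.null(ids) || !all(names(reference$labels) %in% ids)) {
    stop_ac("z_rates row names must cover the reference solution's subjects")
  }
  k <- reference$k
  ref_sets <- split(names(reference$labels), reference$labels)
  ref_means <- lapply(ref_sets, function(s) colMeans(z[s, , drop = FALSE]))

  rows <- list()
  failed <- 0L
  for (r in seq_along(drop_sets)) {
    keep <- setdiff(ids, drop_sets[[r]])
    sol <- try(ward_cluster(z[keep, , drop = FALSE], k = k), silent = TRUE)
    if (inherits(sol, "try-error") ||
        length(unique(sol$labels)) < k) {
      failed <- failed + 1L
      next
    }
    new_sets <- split(names(sol$labels), sol$labels)
    ref_r <- if (restrict_to_retained) {
      lapply(ref_sets, function(s) intersect(s, keep))
    } else ref_sets
    mt <- match_clusters(ref_r, new_sets)
    for (i in seq_len(k)) {
      matched <- new_sets[[mt$perm[i]]]
      pat <- colMeans(z[matched, , drop = FALSE])
      ct <- suppressWarnings(cor.test(pat, ref_means[[i]]))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        resample = r, subtype = i,
        n_retained = length(keep),
        dice = mt$dice[i],
        spatial_cor = unname(ct$estimate),
        cor_p = ct$p.value)
    }
  }
  if (!length(rows)) stop_ac("every resample failed to recluster at k = ", k)
  per <- dplyr::bind_rows(rows)
  per$cor_q <- fdr_adjust(per$cor_p)
  summary <- dplyr::bind_rows(lapply(split(per, per$subtype), function(d) {
    tibble::tibble(subtype = d$subtype[1],
                   dice_mean = mean(d$dice), dice_sd = sd(d$dice),
                   cor_mean = mean(d$spatial_cor), cor_sd = sd(d$spatial_cor),
                   all_q_below_05 = all(d$cor_q < 0.05))
  }))
  structure(list(scheme = scheme, per_resample = per, summary = summary,
                 n_resamples = length(drop_sets), n_failed = failed),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("stability_report (%s): %d resamples, %d failed\n",
              x$scheme, x$n_resamples, x$n_failed))
  print(as.data.frame(x$summary), digits = 3)
  invisible(x)
}

#' Leave-one-out jackknife cluster stability
#'
#' Drops each subject in turn, re-runs Ward clustering at the reference
#' solution's k, matches the perturbed clusters to the reference by
#' maximum-Dice permutation, and records per-subtype Dice (reference
#' membership restricted to retained subjects, so the dropped subject never
#' counts against agreement) plus the Pearson spatial correlation between
#' perturbed and reference cluster-mean atrophy patterns. Correlation
#' p-values are Benjamini-Hochberg adjusted across all resamples x subtypes.
#'
#' @param z_rates subjects x ROIs standardized rate matrix with row names.
#' @param reference [ward_cluster()] solution computed on the same matrix.
#' @param restrict_to_retained score Dice on reference sets restricted to
#'   retained subjects (default) or against the full reference sets.
#' @return object of class `stability_report` with `per_resample` and
#'   `summary` tibbles; degenerate resamples (empty cluster at the cut) are
#'   excluded and counted in `n_failed`.
#' @export
run_jackknife <- function(z_rates, reference, restrict_to_retained = TRUE) {
  stopifnot(inherits(reference, "cluster_solution"))
  ids <- rownames(as.matrix(z_rates))
  stability_engine(z_rates, reference, as.list(ids), "jackknife",
                   restrict_to_retained)
}

#' K-fold cluster stability
#'
#' Partitions subjects into `n_folds` folds (seeded), drops each fold in
#' turn, and scores the reclustering exactly as [run_jackknife()].
#'
#' @inheritParams run_jackknife
#' @param n_folds number of folds (must not exceed n/2).
#' @param seed integer seed for the fold assignment.
#' @return a `stability_report`.
#' @export
run_kfold <- function(z_rates, reference, n_folds = 5, seed = 1L,
                      restrict_to_retained = TRUE) {
  stopifnot(inherits(reference, "cluster_solution"))
  ids <- rownames(as.matrix(z_rates))
  n <- length(ids)
  if (n_folds > n / 2) stop_ac("n_folds must be at most n/2")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)
  fold <- sample(rep(seq_len(n_folds), length.out = n))
  drop_sets <- split(ids, fold)
  stability_engine(z_rates, reference, drop_sets, "kfold",
                   restrict_to_retained)
}
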