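#' Single Motif Cluster Ratio (SMCR)
#'
#' The number of clusters containing a single member divided by the total
#' number of clusters. Used as the constraint during K selection: candidate
#' K values are only admissible when SMCR stays below 5% (default), so the
#' clustering does not fragment into many one-motif clusters.
#'
#' @param assignment vector of cluster ids, one per item.
#' @return ratio in \[0, 1\].
#' @export
smcr <- function(assignment) {
  if (length(assignment) == 0L) stop("empty assignment")
  sizes <- table(assignment)
  sum(sizes == 1L) / length(sizes)
}

#' Seeded K-means clustering
#'
#' Deterministic for a fixed (features, K, seed): the random initialization
#' state is reset before running, mirroring the fixed random-state-0
#' convention used so repeated runs give identical clusterings.
#'
#' @param features numeric matrix, one row per item.
#' @param K number of clusters (must be <= number of rows).
#' @param seed integer random seed (default 0).
#' @param nstart number of random starts (best of; default 10).
#' @return integer vector of cluster ids (1..K), named by rownames.
#' @export
kmeans_cluster <- function(features, K, seed = 0L, nstart = 10L) {
  features <- as.matrix(features)
  if (K > nrow(features)) stop("K = ", K, " exceeds number of items ", nrow(features))
  if (K == nrow(features))  # every item its own cluster
    return(stats::setNames(seq_len(K), rownames(features)))
  set.seed(seed)
  km <- stats::kmeans(features, centers = K, nstart = nstart, iter.max = 100L)
  stats::setNames(km$cluster, rownames(features))
}

# Davies-Bouldin index: mean over clusters of the worst ratio
# (s_i + s_j) / d(c_i, c_j), s = mean member-to-centroid distance
davies_bouldin <- function(features, assignment) {
  features <- as.matrix(features)
  ids <- sort(unique(assignment))
  k <- length(ids)
  if (k < 2L) return(NA_real_)
  cent <- t(vapply(ids, function(c)
    colMeans(features[assignment == c, , drop = FALSE]), numeric(ncol(features))))
  s <- vapply(seq_along(ids), function(ci) {
    x <- features[assignment == ids[ci], , drop = FALSE]
    mean(sqrt(rowSums(sweep(x, 2, cent[ci, ])^2)))
  }, numeric(1))
  Dc <- as.matrix(stats::dist(cent))
  R <- outer(s, s, `+`) / Dc
  diag(R) <- -Inf
  mean(apply(R, 1, max))
}

mean_silhouette <- function(assignment, d) {
  if (length(unique(assignment)) < 2L) return(NA_real_)
  sil <- cluster::silhouette(as.integer(factor(assignment)), d)
  mean(sil[, "sil_width"])
}

#' Default K grid for model selection
#'
#' A sweep from small K up to roughly a quarter of the sample count: all of
#' 2..10 plus a geometric progression up to `ceiling(n / 4)`, capped below n.
#'
#' @param n number of samples.
#' @return sorted integer vector of candidate K values.
#' @export
default_k_grid <- function(n) {
  hi <- max(3L, ceiling(n / 4))
  ks <- 2:10
  if (hi > 10L)
    ks <- c(ks, round(exp(seq(log(11), log(hi), length.out = 8L))))
  sort(unique(pmin(as.integer(ks), n - 1L)))
}

#' Select the number of K-means clusters
#'
#' Runs seeded K-means for every candidate K and scores each clustering by
#' mean silhouette width, Davies-Bouldin index (DBI) and SMCR. Among the K
#' whose SMCR is below `smcr_max`, the chosen K maximises the silhouette;
#' ties break by minimum DBI, then by smallest K. If no candidate meets the
#' SMCR constraint, the K with the smallest SMCR is chosen and flagged.
#'
#' @param features numeric matrix of per-item feature vectors.
#' @param k_grid candidate K values (default [default_k_grid()]).
#' @param smcr_max SMCR admissibility bound (default 0.05, i.e. < 5%).
#' @param seed K-means seed.
#' @return an object of class `k_selection`: data frame `report` (per-K
#'   silhouette, DBI, SMCR), `chosen_k`, `constraint_met`, `smcr_max`,
#'   `seed`.
#' @export
select_k <- function(features, k_grid = NULL, smcr_max = 0.05, seed = 0L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (is.null(k_grid)) k_grid <- default_k_grid(n)
  if (length(k_grid) == 0L) stop("empty k_grid")
  if (any(k_grid >= n)) stop("every candidate K must be < number of samples")
  d <- stats::dist(features)
  rows <- lapply(k_grid, function(K) {
    cl <- kmeans_cluster(features, K, seed)
    data.frame(k = K,
               silhouette = mean_silhouette(cl, d),
               dbi = davies_bouldin(features, cl),
               smcr = smcr(cl))
  })
  report <- do.call(rbind, rows)
  ok <- report$smcr < smcr_max
  if (any(ok)) {
    cand <- report[ok, ]
    cand <- cand[order(-cand$silhouette, cand$dbi, cand$k), ]
    chosen <- cand$k[1]; met <- TRUE
  } else {
    chosen <- report$k[order(report$smcr, report$k)][1]; met <- FALSE
  }
  structure(list(report = report, chosen_k = chosen, constraint_met = met,
                 smcr_max = smcr_max, seed = seed),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("<k_selection> chosen K =", x$chosen_k,
      if (x$constraint_met) sprintf("(SMCR < %g satisfied)", x$smcr_max)
      else "(no K met the SMCR constraint; min-SMCR fallback)", "\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Agglomerative subclustering inside each K-means cluster
#'
#' Runs hierarchical agglomerative clustering (Euclidean metric, average
#' linkage by default) independently within each cluster and cuts the
#' dendrogram at `distance_threshold`. Tight clusters stay single
#' subclusters; heterogeneous clusters split. Subclusters never cross
#' cluster boundaries, so the subclustering refines the clustering.
#'
#' @param features numeric matrix of per-item features.
#' @param assignment cluster id vector from [kmeans_cluster()].
#' @param linkage hclust agglomeration method (default `"average"`).
#' @param distance_threshold dendrogram cut height (default 6, in embedding
#'   units; tuned spaces may need other values, so it is exposed).
#' @return data frame `loop_id, cluster, subcluster` where `subcluster` is
#'   `"<cluster>.<local>"` and nests within `cluster`.
#' @export
subcluster <- function(features, assignment, linkage = "average",
                       distance_threshold = 6) {
  stopifnot(distance_threshold > 0)
  features <- as.matrix(features)
  ids <- rownames(features)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(features)))
  out <- data.frame(loop_id = ids, cluster = as.integer(assignment),
                    subcluster = NA_character_, stringsAsFactors = FALSE)
  for (c in sort(unique(out$cluster))) {
    rows <- which(out$cluster == c)
    if (length(rows) == 1L) {
      out$subcluster[rows] <- paste0(c, ".1")
      next
    }
    hc <- stats::hclust(stats::dist(features[rows, , drop = FALSE]),
                        method = linkage)
    local <- stats::cutree(hc, h = distance_threshold)
    out$subcluster[rows] <- paste0(c, ".", local)
  }
  out
}

#' Compare two clusterings by ARI and AMI
#'
#' Standard adjusted Rand index (pair-counting, chance-corrected; can be
#' negative for worse-than-chance agreement) and adjusted mutual information
#' (exact expected MI under the hypergeometric model, arithmetic-mean
#' normalizer).
#'
#' @param pred,truth label vectors over the same items (named vectors are
#'   aligned by name).
#' @return list with `ari` and `ami`.
#' @export
compare_clusterings <- function(pred, truth) {
  if (!is.null(names(pred)) && !is.null(names(truth))) {
    if (!setequal(names(pred), names(truth)))
      stop("pred and truth refer to different item sets")
    truth <- truth[names(pred)]
  } else if (length(pred) != length(truth)) {
    stop("pred and truth must cover the same items")
  }
  list(ari = mclust::adjustedRandIndex(pred, truth),
       ami = adjusted_mutual_information(pred, truth))
}

#' Adjusted mutual information between two partitions
#'
#' AMI = (MI - E\[MI\]) / (mean(H(U), H(V)) - E\[MI\]) with the exact
#' expectation of mutual information under the permutation (hypergeometric)
#' model.
#'
#' @param a,b label vectors of equal length.
#' @return AMI value (1 for identical partitions, about 0 for independent
#'   ones).
#' @export
adjusted_mutual_information <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  ai <- rowSums(tab); bj <- colSums(tab)
  H <- function(x) { p <- x[x > 0] / sum(x); -sum(p * log(p)) }
  mi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + (nij / n) * log(n * nij / (ai[i] * bj[j]))
  }
  emi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    lo <- max(ai[i] + bj[j] - n, 1)
    hi <- min(ai[i], bj[j])
    if (lo > hi) next
    for (nij in lo:hi) {
      lp <- lgamma(ai[i] + 1) - lgamma(nij + 1) - lgamma(ai[i] - nij + 1) +
        lgamma(n - ai[i] + 1) - lgamma(bj[j] - nij + 1) -
        lgamma(n - ai[i] - bj[j] + nij + 1) +
        lgamma(bj[j] + 1) + lgamma(n - bj[j] + 1) - lgamma(n + 1)
      emi <- emi + (nij / n) * log(n * nij / (ai[i] * bj[j])) * exp(lp)
    }
  }
  denom <- mean(c(H(ai), H(bj))) - emi
  if (abs(denom) < 1e-15) return(if (abs(mi - emi) < 1e-15) 1 else 0)
  unname((mi - emi) / denom)
}
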