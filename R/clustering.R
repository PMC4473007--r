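#' k-means clustering of promoter signal
#'
#' Lloyd iterations with Euclidean distance, k-means++ initialization and
#' best-of-`n_restarts` selection by within-cluster sum of squares
#' (inertia). An emptied cluster is repaired by reseeding its centroid at
#' the point farthest from its current centroid. Rows are used on the
#' normalized scale without per-row standardization, so enrichment
#' magnitude stays part of the signal. Deterministic given `seed`.
#'
#' @param mat Numeric matrix, genes x bins (e.g. from [promoter_matrix()]).
#' @param k Number of clusters (2 <= k <= nrow).
#' @param seed Integer seed.
#' @param n_restarts Independent initializations (default 10).
#' @param max_iter Maximum Lloyd iterations per restart.
#' @return List of class `cluster_result`: k, assignments (named integer,
#'   labels 1..k), centroids (k x bins), inertia, sizes.
#' @export
cluster_promoters <- function(mat, k, seed = 1L, n_restarts = 10,
                              max_iter = 100) {
  if (!nrow(mat)) stop("empty matrix")
  if (k < 1) stop("k must be at least 1")
  if (k > nrow(mat)) stop(sprintf("k = %d exceeds the %d rows available",
                                  k, nrow(mat)))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- .lloyd(mat, .kmeanspp_init(mat, k), max_iter)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  structure(list(k = k,
                 assignments = setNames(best$cluster, rownames(mat)),
                 centroids = best$centers,
                 inertia = best$inertia,
                 sizes = tabulate(best$cluster, k)),
            class = "cluster_result")
}

# squared Euclidean distance of every row of m to every row of centers
.sqdist <- function(m, centers) {
  d <- outer(rowSums(m^2), rowSums(centers^2), "+") - 2 * m %*% t(centers)
  pmax(d, 0)
}

.kmeanspp_init <- function(m, k) {
  n <- nrow(m)
  centers <- m[sample.int(n, 1), , drop = FALSE]
  while (nrow(centers) < k) {
    d2 <- apply(.sqdist(m, centers), 1, min)
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers <- rbind(centers, m[sample.int(n, 1, prob = p), , drop = FALSE])
  }
  unname(centers)
}

.lloyd <- function(m, centers, max_iter) {
  k <- nrow(centers)
  cl <- integer(nrow(m))
  for (it in seq_len(max_iter)) {
    d <- .sqdist(m, centers)
    new_cl <- max.col(-d, ties.method = "first")
    for (j in seq_len(k)) {              # empty-cluster repair
      if (!any(new_cl == j)) {
        owners <- which(tabulate(new_cl, k)[new_cl] > 1)
        far <- owners[which.max(d[cbind(owners, new_cl[owners])])]
        new_cl[far] <- j
      }
    }
    for (j in seq_len(k))
      centers[j, ] <- colMeans(m[new_cl == j, , drop = FALSE])
    if (identical(new_cl, cl)) break
    cl <- new_cl
  }
  d <- .sqdist(m, centers)
  list(cluster = cl, centers = centers,
       inertia = sum(d[cbind(seq_len(nrow(m)), cl)]))
}

#' Sort a clustered matrix by expression and summarize per-cluster expression
#'
#' Orders rows by cluster, then by descending expression within each
#' cluster, and returns the sorted matrix together with cluster boundaries
#' and five-number expression summaries -- the data behind a sorted heatmap
#' and the accompanying expression box plot. Genes without an expression
#' value are dropped with a warning.
#'
#' @param mat The matrix that was clustered.
#' @param result A `cluster_result` from [cluster_promoters()].
#' @param expression Named numeric vector (or data.frame gene_id, value) of
#'   log2 expression.
#' @return List: `matrix` (sorted), `order` (row indices into `mat`),
#'   `boundaries` (last row of each cluster in the sorted matrix),
#'   `expression_summary` (cluster, n, min, q1, median, q3, max, mean).
#' @export
sort_and_render <- function(mat, result, expression) {
  if (is.data.frame(expression))
    expression <- setNames(expression$value, expression$gene_id)
  ev <- expression[rownames(mat)]
  miss <- is.na(ev)
  if (any(miss)) {
    warning(sprintf("%d gene(s) without expression dropped from rendering",
                    sum(miss)))
  }
  keep <- which(!miss)
  cl <- result$assignments[rownames(mat)][keep]
  o <- keep[order(cl, -ev[keep], rownames(mat)[keep])]
  sorted <- mat[o, , drop = FALSE]
  cl_sorted <- result$assignments[rownames(sorted)]
  summ <- do.call(rbind, lapply(seq_len(result$k), function(j) {
    v <- ev[names(result$assignments)[result$assignments == j]]
    v <- v[!is.na(v)]
    if (!length(v))
      return(data.frame(cluster = j, n = 0L, min = NA, q1 = NA, median = NA,
                        q3 = NA, max = NA, mean = NA))
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(cluster = j, n = length(v), min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5], mean = mean(v))
  }))
  list(matrix = sorted, order = o,
       boundaries = cumsum(rle(as.integer(cl_sorted))$lengths),
       expression_summary = summ)
}
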