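#' Hierarchical clustering of DE features on per-condition mean TPM
#'
#' Computes, per feature, the mean TPM across the replicates of each
#' condition, takes the distance `d = 1 - Pearson r` between feature rows,
#' and agglomerates with the Lance-Williams centroid update. Merge ties are
#' broken deterministically in favour of the cluster pair containing the
#' smallest original feature index. A zero-variance row has no defined
#' correlation and is assigned the maximal distance 2 to every other row,
#' with a warning.
#'
#' @param tpm TPM matrix (features x samples), typically restricted to DE
#'   features.
#' @param condition factor of condition labels per sample.
#' @return A list with `hclust` (an `stats::hclust`-compatible tree),
#'   `order` (row order for plotting), `cond_means` (features x conditions)
#'   and `scaled` (row-normalised means for heat-map display).
#' @export
cluster_heatmap <- function(tpm, condition) {
  tpm <- as.matrix(tpm)
  if (nrow(tpm) < 2L) stop("need >= 2 features to cluster")
  condition <- as.factor(condition)
  cond_means <- vapply(levels(condition), function(cc) {
    rowMeans(tpm[, condition == cc, drop = FALSE])
  }, numeric(nrow(tpm)))
  rownames(cond_means) <- rownames(tpm)
  d <- pearson_distance(cond_means)
  hc <- centroid_agglomerate(d, labels = rownames(cond_means))
  rs <- apply(cond_means, 1, sd)
  rs[rs == 0] <- 1
  scaled <- (cond_means - rowMeans(cond_means)) / rs
  list(hclust = hc, order = hc$order, cond_means = cond_means,
       scaled = scaled)
}

# 1 - Pearson correlation between rows; zero-variance rows get distance 2.
pearson_distance <- function(m) {
  v <- apply(m, 1, sd)
  if (any(v == 0)) {
    warning("zero-variance feature row(s); assigned maximal distance 2")
  }
  d <- matrix(2, nrow(m), nrow(m))
  ok <- v > 0
  if (sum(ok) >= 2) {
    d[ok, ok] <- 1 - cor(t(m[ok, , drop = FALSE]))
  }
  diag(d) <- 0
  d
}

# Agglomerative clustering with the Lance-Williams centroid update on a full
# distance matrix; returns an hclust-compatible object. Ties pick the pair
# whose smallest original member index is lowest (then the second index).
centroid_agglomerate <- function(d, labels = NULL) {
  n <- nrow(d)
  active <- seq_len(n)
  sizes <- rep(1L, n)
  cluster_id <- -seq_len(n)          # hclust convention: negatives = leaves
  min_member <- seq_len(n)           # for deterministic tie-breaking
  members <- as.list(seq_len(n))
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  order_list <- as.list(seq_len(n))
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    best <- NULL
    for (ii in seq_len(k - 1L)) {
      for (jj in seq.int(ii + 1L, k)) {
        i <- active[ii]; j <- active[jj]
        dij <- d[i, j]
        key <- c(dij, min(min_member[i], min_member[j]),
                 max(min_member[i], min_member[j]))
        if (is.null(best) || key_less(key, best$key)) {
          best <- list(i = i, j = j, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    ni <- sizes[i]; nj <- sizes[j]
    height[step] <- d[i, j]
    merge[step, ] <- sort_merge(cluster_id[i], cluster_id[j])
    # Lance-Williams centroid update against every other active cluster
    for (m_ in setdiff(active, c(i, j))) {
      d[i, m_] <- d[m_, i] <-
        (ni * d[i, m_] + nj * d[j, m_]) / (ni + nj) -
        (ni * nj * d[i, j]) / (ni + nj)^2
    }
    sizes[i] <- ni + nj
    min_member[i] <- min(min_member[i], min_member[j])
    members[[i]] <- c(members[[i]], members[[j]])
    order_list[[i]] <- c(order_list[[i]], order_list[[j]])
    cluster_id[i] <- step
    active <- setdiff(active, j)
  }
  structure(list(merge = merge, height = height,
                 order = order_list[[active]],
                 labels = labels, method = "centroid",
                 dist.method = "1 - pearson"),
            class = "hclust")
}

key_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

sort_merge <- function(a, b) {
  # hclust lists singletons (negative) before clusters, else ascending
  if (a < 0 && b < 0) c(min(a, b), max(a, b))
  else if (a < 0) c(a, b)
  else if (b < 0) c(b, a)
  else c(min(a, b), max(a, b))
}
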