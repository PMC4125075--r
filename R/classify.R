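# Hierarchical signature clustering, Davies-Bouldin scoring, period
# selection, and the leave-one-out misclassification analysis.

#' Hierarchical clustering of signature features
#'
#' Agglomerative clustering with average linkage and Euclidean distance —
#' the standard dendrogram construction for signature vectors — cut into
#' `k` groups.
#'
#' @param features n x d numeric matrix (rows = samples); row names are
#'   used as leaf labels.
#' @param k number of clusters to cut the tree into.
#' @return object of class `clustering_result`: `hclust` (the merge tree),
#'   `labels` (integer cluster per sample), `k`.
#' @export
hcluster <- function(features, k) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 2 || ncol(features) < 1) stop("hcluster: need n >= 2, d >= 1")
  if (any(!is.finite(features))) stop("hcluster: non-finite features")
  if (k > n) stop("hcluster: k must not exceed the number of samples")
  if (is.null(rownames(features)))
    rownames(features) <- paste0("s", seq_len(n))
  hc <- stats::hclust(stats::dist(features, method = "euclidean"),
                      method = "average")
  labels <- stats::cutree(hc, k = k)
  structure(list(hclust = hc, labels = unname(labels), k = k,
                 names = rownames(features)),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> %d samples cut into %d clusters\n",
              length(x$labels), x$k))
  invisible(x)
}

#' Davies-Bouldin cluster quality score
#'
#' \deqn{DB = \frac{1}{K} \sum_i \max_{j \ne i} \frac{S_i + S_j}{M_{ij}}}
#' where \eqn{S_i} is the mean Euclidean distance of cluster members to
#' their centroid and \eqn{M_{ij}} the distance between centroids. Smaller
#' scores mean more distinct clusters. Coincident centroids give `Inf`.
#'
#' @param features n x d numeric matrix.
#' @param labels cluster assignment per row (>= 2 nonempty clusters).
#' @return non-negative scalar (possibly `Inf`).
#' @export
davies_bouldin <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.integer(factor(labels))
  ks <- sort(unique(labels))
  if (length(ks) < 2) stop("davies_bouldin: need at least 2 clusters")
  cent <- do.call(rbind, lapply(ks, function(g)
    colMeans(features[labels == g, , drop = FALSE])))
  S <- vapply(ks, function(g) {
    m <- features[labels == g, , drop = FALSE]
    mean(sqrt(rowSums((m - rep(cent[g, ], each = nrow(m)))^2)))
  }, numeric(1))
  K <- length(ks)
  M <- as.matrix(stats::dist(cent))
  ratio <- outer(S, S, `+`) / M
  coincident <- M == 0
  diag(coincident) <- FALSE
  ratio[coincident] <- Inf
  diag(ratio) <- -Inf
  mean(apply(ratio, 1, max))
}

#' Select the most informative wavelet period
#'
#' Scores every period on the shared grid by the Davies-Bouldin index of
#' the per-sample signature vectors at that period, clustered by the known
#' groups, and returns the period with the minimal score. Periods at which
#' all features are identical (e.g. all zero) score `Inf`. An optional
#' exclusion mask removes uninformative period ranges from consideration.
#'
#' @param signatures list of [wavelet_transform()] results on one shared
#'   period grid.
#' @param true_groups group label per signature.
#' @param exclude optional logical vector over the period grid; `TRUE`
#'   periods are skipped.
#' @return list with `period` (hours), `db_by_period` (score profile),
#'   `periods`, and `degenerate` (TRUE when no period had a finite score).
#' @export
choose_period <- function(signatures, true_groups, exclude = NULL) {
  stopifnot(length(signatures) >= 2,
            length(true_groups) == length(signatures))
  periods <- signatures[[1]]$periods
  for (s in signatures)
    if (!isTRUE(all.equal(s$periods, periods)))
      stop("choose_period: signatures must share one period grid")
  if (is.null(exclude)) exclude <- rep(FALSE, length(periods))
  db <- vapply(seq_along(periods), function(i) {
    if (exclude[i]) return(Inf)
    feats <- t(vapply(signatures, function(s) s$coef[i, ],
                      numeric(ncol(signatures[[1]]$coef))))
    if (all(apply(feats, 2, function(col) diff(range(col)) == 0))) return(Inf)
    davies_bouldin(feats, true_groups)
  }, numeric(1))
  degenerate <- all(!is.finite(db))
  best <- if (degenerate) 1L else which.min(db)
  list(period = periods[best], db_by_period = db, periods = periods,
       degenerate = degenerate)
}

# All permutations of 1..n (n <= 8 in any use here).
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub), n - 1L))
  }))
}

#' Minimal misclassification count under optimal label matching
#'
#' Cluster labels are arbitrary, so the number of misclassified samples is
#' the minimum, over assignments of predicted clusters to true groups, of
#' the samples falling outside their assigned group. Computed exactly by
#' scanning label permutations (group counts here are small).
#'
#' @param pred_labels predicted cluster per sample.
#' @param true_groups true group per sample.
#' @return integer count in `[0, n]`.
#' @export
misclassification_count <- function(pred_labels, true_groups) {
  stopifnot(length(pred_labels) == length(true_groups))
  p <- as.integer(factor(pred_labels))
  g <- as.integer(factor(true_groups))
  np <- max(p); ng <- max(g)
  conf <- matrix(0L, np, ng)
  for (i in seq_along(p)) conf[p[i], g[i]] <- conf[p[i], g[i]] + 1L
  m <- max(np, ng)
  if (m > 8) stop("misclassification_count: more than 8 groups not supported")
  full <- matrix(0L, m, m)
  full[seq_len(np), seq_len(ng)] <- conf
  perms <- .permutations(m)
  hits <- apply(perms, 1, function(pp) sum(full[cbind(seq_len(m), pp)]))
  length(p) - max(hits)
}

#' Leave-one-out misclassification analysis
#'
#' Drops each sample in turn, re-clusters the remaining samples into `k`
#' groups and counts the permutation-minimal misclassifications against
#' the true groups. Every group must have at least two members.
#'
#' @param features n x d numeric matrix.
#' @param true_groups true group per row.
#' @param k number of clusters (defaults to the number of groups).
#' @return list with `counts` (misclassified count per left-out sample)
#'   and `histogram` (a `table` of the counts).
#' @export
bootstrap_misclassification <- function(features, true_groups, k = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  tg <- as.integer(factor(true_groups))
  if (any(table(tg) < 2))
    stop("bootstrap_misclassification: every group needs >= 2 members")
  if (is.null(k)) k <- max(tg)
  counts <- vapply(seq_len(n), function(i) {
    res <- hcluster(features[-i, , drop = FALSE], k)
    misclassification_count(res$labels, tg[-i])
  }, numeric(1))
  list(counts = counts, histogram = table(factor(counts, levels = 0:max(counts))))
}

#' Export a dendrogram as a Newick string
#'
#' Converts the merge tree of a [hcluster()] result to Newick with merge
#' heights as branch lengths (via [ape::as.phylo()]).
#'
#' @param result a `clustering_result`.
#' @return single Newick string.
#' @export
export_dendrogram <- function(result) {
  stopifnot(inherits(result, "clustering_result"))
  phy <- ape::as.phylo(result$hclust)
  ape::write.tree(phy)
}

#' Between-group separation relative to within-group scatter
#'
#' For two or more labeled groups of feature vectors, returns the mean
#' between-centroid distance divided by the mean within-group distance to
#' the centroid — a scale-free separation ratio used to quantify the gain
#' from condition multiplexing.
#'
#' @param features n x d matrix.
#' @param groups label per row.
#' @return positive scalar (`Inf` for zero scatter).
#' @export
separation_ratio <- function(features, groups) {
  features <- as.matrix(features)
  g <- as.integer(factor(groups))
  ks <- sort(unique(g))
  stopifnot(length(ks) >= 2)
  cent <- do.call(rbind, lapply(ks, function(i)
    colMeans(features[g == i, , drop = FALSE])))
  S <- vapply(ks, function(i) {
    m <- features[g == i, , drop = FALSE]
    mean(sqrt(rowSums((m - rep(cent[i, ], each = nrow(m)))^2)))
  }, numeric(1))
  between <- mean(stats::dist(cent))
  between / mean(S)
}
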