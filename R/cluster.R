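linkage_methods <- c(
  single = "single", complete = "complete", average = "average",
  centroid = "centroid", ward = "ward.D"
)

#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Runs agglomerative clustering on a precomputed distance matrix with one of
#' five linkage rules: `single`, `complete`, `average`, `centroid` or `ward`.
#' The Lance-Williams update of the chosen linkage is applied directly to the
#' supplied dissimilarities (for Ward this is [stats::hclust()]'s `"ward.D"`;
#' shifted alignment scores are not Euclidean, which is a documented
#' methodological caveat of the whole approach, not of this function).
#'
#' @param D A `tnw_dist` matrix from [to_distance()], a symmetric matrix, or
#'   a [stats::dist] object.
#' @param linkage One of `"ward"` (default), `"single"`, `"complete"`,
#'   `"average"`, `"centroid"`.
#' @return An [stats::hclust] dendrogram (N - 1 merges over N leaves).
#' @examples
#' D <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3, 3)
#' agglomerate(D, "single")
#' @export
agglomerate <- function(D, linkage = "ward") {
  if (!linkage %in% names(linkage_methods)) {
    stop(sprintf("unknown linkage '%s'; use one of %s", linkage,
                 paste(names(linkage_methods), collapse = ", ")), call. = FALSE)
  }
  d <- if (inherits(D, "dist")) D else stats::as.dist(unclass(D))
  Z <- stats::hclust(d, method = linkage_methods[[linkage]])
  Z$linkage <- linkage
  Z
}

#' Cut a dendrogram into q clusters
#'
#' Undoes the last `q - 1` merges of the dendrogram, yielding exactly `q`
#' non-empty groups.
#'
#' @param Z An [stats::hclust] object from [agglomerate()].
#' @param q Number of clusters, `1 <= q <= N`.
#' @return An integer label vector (named by the leaf labels when present).
#' @examples
#' D <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3, 3)
#' cut_clusters(agglomerate(D, "single"), 2)
#' @export
cut_clusters <- function(Z, q) {
  n <- length(Z$order)
  if (q < 1L || q > n) {
    stop(sprintf("q = %d out of range [1, %d]", q, n), call. = FALSE)
  }
  stats::cutree(Z, k = q)
}
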