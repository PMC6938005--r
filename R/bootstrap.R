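# Deterministic seed schedule: replicate r of gap-grid position j is a pure
# function of (seed, j, r), so adding grid points or replicates never
# perturbs the draws of existing ones. Kept below 2^31 - 1 (R integer range).
derive_seed <- function(seed, j, r) {
  as.integer(((seed %% 1e6) * 2099 + j * 1000003 + r * 7919) %% 2147483647)
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

boot_indices <- function(n, seed, j, r) {
  local_seed(derive_seed(seed, j, r), sample.int(n, n, replace = TRUE))
}

# One bootstrap replicate of the cluster-number validation: cluster the
# induced sub-distance-matrix of the resample, and for each q compare the
# resample's clustering against the original clustering restricted to the
# drawn multiset (each drawn copy is an element; its "original" label is that
# of the subject it copies).
boot_compare_one <- function(Z, D, idx, k_min, k_max, linkage) {
  Db <- unclass(D)[idx, idx, drop = FALSE]
  Zb <- agglomerate(Db, linkage)
  purrr::map_dfr(k_min:k_max, function(q) {
    orig <- unname(cut_clusters(Z, q))[idx]
    boot <- unname(cut_clusters(Zb, q))
    dplyr::bind_cols(tibble::tibble(q = q), compare_partitions(orig, boot))
  })
}

#' Bootstrap statistics of partition-comparison indices over cluster numbers
#'
#' The cluster-number validation: the full data are clustered once, then `M`
#' bootstrap resamples (subjects drawn uniformly with replacement) are each
#' clustered from the induced sub-distance-matrix, both dendrograms are cut
#' at every `q` between `k_min` and `k_max`, and the five
#' partition-comparison indices of [compare_partitions()] are computed
#' between the original clustering (restricted to the resampled multiset)
#' and the resample's clustering. A `q` whose indices are high and tight
#' across resamples is well supported by the data.
#'
#' @param D Distance matrix ([to_distance()] output or any symmetric matrix).
#' @param M Number of bootstrap resamples.
#' @param linkage Linkage rule, see [agglomerate()].
#' @param k_min,k_max Range of cluster numbers to evaluate,
#'   `2 <= k_min <= k_max <= N`.
#' @param seed Integer seed; replicate `r` draws are a deterministic function
#'   of `(seed, r)`.
#' @param .gap_index Internal offset in the seed schedule used by the
#'   gap-penalty sweep; leave at 0 when calling directly.
#' @return A tibble of class `index_stats`: one row per `(q, index)` with the
#'   `median`, `mean`, `variance` and `sd` of the index over the `M`
#'   replicates. Attributes `M`, `linkage`, `seed`, `k_min`, `k_max` record
#'   the run configuration.
#' @examples
#' D <- to_distance(similarity_matrix(list("0.A", "0.A", "0.B", "0.B")))
#' bootstrap_index_stats(D, M = 20, k_min = 2, k_max = 3, seed = 1)
#' @export
bootstrap_index_stats <- function(D, M = 1000, linkage = "ward", k_min = 2,
                                  k_max = NULL, seed = 42, .gap_index = 0) {
  n <- nrow(unclass(D))
  k_max <- k_max %||% min(30L, n - 1L)
  if (M < 1L) stop("M must be >= 1", call. = FALSE)
  if (k_min < 2L || k_min > k_max || k_max > n) {
    stop("require 2 <= k_min <= k_max <= N", call. = FALSE)
  }
  Z <- agglomerate(D, linkage)
  reps <- purrr::map_dfr(seq_len(M), function(r) {
    idx <- boot_indices(n, seed, .gap_index, r)
    dplyr::bind_cols(
      tibble::tibble(replicate = r),
      boot_compare_one(Z, D, idx, k_min, k_max, linkage)
    )
  })
  stats <- reps |>
    tidyr::pivot_longer(dplyr::all_of(index_names), names_to = "index",
                        values_to = "value") |>
    dplyr::group_by(.data$q, .data$index) |>
    dplyr::summarise(
      median = stats::median(.data$value),
      mean = mean(.data$value),
      variance = stats::var(.data$value),
      sd = stats::sd(.data$value),
      .groups = "drop"
    ) |>
    dplyr::mutate(index = factor(.data$index, levels = index_names)) |>
    dplyr::arrange(.data$q, .data$index) |>
    dplyr::mutate(index = as.character(.data$index))
  structure(stats, class = c("index_stats", class(stats)),
            M = M, linkage = linkage, seed = seed,
            k_min = k_min, k_max = k_max, dendrogram = Z)
}

# Stability measures of the original clusters against one resample's
# clustering. Intersections count bootstrap multiplicities; an original
# cluster with no drawn copies scores 0 on all three measures.
stability_one <- function(D, labels, idx, linkage, cluster_ids) {
  k <- length(cluster_ids)
  Zb <- agglomerate(unclass(D)[idx, idx, drop = FALSE], linkage)
  B <- unname(cut_clusters(Zb, k))
  A <- labels[idx]
  size_b <- tabulate(B, nbins = k)
  purrr::map_dfr(cluster_ids, function(cl) {
    in_a <- A == cl
    size_a <- sum(in_a)
    if (size_a == 0L) {
      return(tibble::tibble(cluster = cl, tau = 0, gamma = 0, eta = 0))
    }
    inter <- tabulate(B[in_a], nbins = k)
    # best match: maximal overlap; ties by larger Jaccard, then lowest label
    tau_all <- inter / (size_a + size_b - inter)
    tau_all[is.nan(tau_all)] <- 0
    cand <- which(inter == max(inter))
    best <- cand[order(-tau_all[cand], cand)][1L]
    tibble::tibble(
      cluster = cl,
      tau = tau_all[best],
      gamma = inter[best] / size_a,
      eta = 2 * inter[best] / (size_a + size_b[best])
    )
  })
}

#' Per-cluster stability by bootstrap resampling
#'
#' Assesses how stable each cluster of a chosen partition is: for each of `M`
#' bootstrap resamples, the resample is re-clustered (induced
#' sub-distance-matrix, same linkage) and cut into the same number of
#' clusters `k`; each original cluster is then matched to the resample
#' cluster with maximal overlap (multiplicities counted), and three measures
#' are recorded — the Jaccard index `tau`, the recovery rate `gamma`
#' (fraction of the original cluster's drawn members found in the matched
#' cluster) and the Dice coefficient `eta`. Medians, averages and standard
#' deviations over replicates summarise each cluster's stability; all three
#' measures lie in `[0, 1]` and higher is more stable.
#'
#' @param D Distance matrix over the N subjects.
#' @param labels Cluster label vector of length N with `k >= 2` distinct
#'   values (e.g. from [cut_clusters()]).
#' @inheritParams bootstrap_index_stats
#' @return A tibble of class `stability_report`: one row per
#'   `(cluster, measure)` with the cluster `size` and the `median`, `average`
#'   and `sd` over replicates; `measure` is one of `"tau"`, `"gamma"`,
#'   `"eta"`.
#' @examples
#' D <- to_distance(similarity_matrix(list("0.A", "0.A", "0.B", "0.B")))
#' labels <- cut_clusters(agglomerate(D), 2)
#' cluster_stability(D, labels, M = 20, seed = 1)
#' @export
cluster_stability <- function(D, labels, linkage = "ward", M = 1000,
                              seed = 42, .gap_index = 0) {
  n <- nrow(unclass(D))
  labels <- unname(labels)
  if (length(labels) != n) {
    stop("`labels` must assign one cluster per row of D", call. = FALSE)
  }
  cluster_ids <- sort(unique(labels))
  if (length(cluster_ids) < 2L) stop("need k >= 2 clusters", call. = FALSE)
  reps <- purrr::map_dfr(seq_len(M), function(r) {
    idx <- boot_indices(n, seed, .gap_index, r)
    dplyr::bind_cols(
      tibble::tibble(replicate = r),
      stability_one(D, labels, idx, linkage, cluster_ids)
    )
  })
  sizes <- tibble::tibble(
    cluster = cluster_ids,
    size = vapply(cluster_ids, function(cl) sum(labels == cl), integer(1L))
  )
  report <- reps |>
    tidyr::pivot_longer(c("tau", "gamma", "eta"), names_to = "measure",
                        values_to = "value") |>
    dplyr::group_by(.data$cluster, .data$measure) |>
    dplyr::summarise(
      median = stats::median(.data$value),
      average = mean(.data$value),
      sd = stats::sd(.data$value),
      .groups = "drop"
    ) |>
    dplyr::left_join(sizes, by = "cluster") |>
    dplyr::relocate("size", .after = "cluster") |>
    dplyr::mutate(measure = factor(.data$measure,
                                   levels = c("tau", "gamma", "eta"))) |>
    dplyr::arrange(.data$cluster, .data$measure) |>
    dplyr::mutate(measure = as.character(.data$measure))
  structure(report, class = c("stability_report", class(report)),
            M = M, linkage = linkage, seed = seed)
}
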