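#' Full clustering pipeline with gap-penalty sweep
#'
#' End-to-end orchestration: for every gap penalty on the grid, align all
#' sequence pairs with the temporal Needleman-Wunsch algorithm
#' ([similarity_matrix()]), convert scores to distances ([to_distance()]),
#' and run the bootstrap cluster-number validation
#' ([bootstrap_index_stats()]). The number of clusters `k` and the gap
#' penalty `g` are then selected (automatically via [select_k()], or left to
#' the user in semi-automatic mode, where the full statistics tables and
#' dendrograms are returned for inspection), and the stability of the final
#' clusters is assessed with [cluster_stability()].
#'
#' The bootstrap seed schedule derives replicate `r` of gap-grid position
#' `j` deterministically from `(seed, j, r)`, so runs are bit-reproducible
#' and extending the grid does not perturb existing replicates.
#'
#' @param seqs A sequence tibble (see [pe_tbl()]) or list of `pe_seq`
#'   objects / PE strings.
#' @param g_min,g_max,g_step Gap-penalty grid `g_min, g_min + g_step, ...`
#'   up to `g_max` (defaults 0, 1, 0.1).
#' @param match,mismatch,temporal Scoring parameters, see
#'   [scoring_scheme()].
#' @param M Bootstrap replicates per grid position (default 1000).
#' @param linkage Linkage rule (default `"ward"`).
#' @param k_min,k_max Cluster-number range (defaults 2 and `min(30, N - 1)`).
#' @param mode `"automatic"` (select `k` and `g` by the modal-argmax rule)
#'   or `"semi-automatic"` (no selection; `choose()` on the result, or
#'   inspect `tidy()` output, then call [cluster_stability()] yourself).
#' @param chosen_k,chosen_g In semi-automatic mode, the user's choice; if
#'   supplied, stability is computed for it.
#' @param seed Integer seed governing all resampling.
#' @return A `tnw_sweep` object: a list with `stats` (tibble of per-(g, q,
#'   index) bootstrap statistics), `selection` (`k`, `g`, and the per-index
#'   votes), `partition` (tibble `patient_id`, `cluster` at the selection),
#'   `stability` (a [cluster_stability()] report), `dendrograms` (one
#'   [stats::hclust] per grid value), `similarity` and `distance` matrices
#'   at the selected `g`, and `config`.
#' @examples
#' ds <- make_two_cluster_dataset(n_per_cluster = 5, seed = 1)
#' sw <- run_sweep(ds, g_min = 0.7, g_max = 0.7, M = 20, k_max = 4, seed = 1)
#' glance(sw)
#' @export
run_sweep <- function(seqs, g_min = 0, g_max = 1, g_step = 0.1,
                      match = 1, mismatch = -1.1, temporal = 0.25,
                      M = 1000, linkage = "ward", k_min = 2, k_max = NULL,
                      mode = c("automatic", "semi-automatic"),
                      chosen_k = NULL, chosen_g = NULL, seed = 42) {
  mode <- match.arg(mode)
  sl <- seq_list(seqs)
  n <- length(sl)
  if (n < 2L) stop("need at least two sequences", call. = FALSE)
  if (g_min > g_max || g_step <= 0) stop("invalid gap grid", call. = FALSE)
  grid <- seq(g_min, g_max, by = g_step)
  if (length(grid) == 0L) stop("empty gap grid", call. = FALSE)
  k_max <- k_max %||% min(30L, n - 1L)

  per_gap <- purrr::map(seq_along(grid), function(j) {
    g <- grid[j]
    S <- similarity_matrix(sl, scoring_scheme(match, mismatch, g, temporal))
    D <- to_distance(S)
    st <- bootstrap_index_stats(D, M = M, linkage = linkage, k_min = k_min,
                                k_max = k_max, seed = seed, .gap_index = j)
    list(g = g, S = S, D = D, stats = st, Z = attr(st, "dendrogram"))
  })
  stats_tbl <- purrr::map_dfr(per_gap, function(x) {
    dplyr::bind_cols(tibble::tibble(g = x$g), tibble::as_tibble(x$stats))
  })

  selection <- NULL
  partition <- NULL
  stability <- NULL
  S_sel <- NULL
  D_sel <- NULL
  if (mode == "automatic") {
    selection <- select_k(stats_tbl)
  } else if (!is.null(chosen_k)) {
    selection <- list(k = chosen_k, g = chosen_g %||% grid[1L], votes = NULL)
  }
  if (!is.null(selection)) {
    j_sel <- which.min(abs(grid - selection$g))
    sel <- per_gap[[j_sel]]
    S_sel <- sel$S
    D_sel <- sel$D
    labels <- cut_clusters(sel$Z, selection$k)
    partition <- tibble::tibble(patient_id = names(sl),
                                cluster = unname(labels))
    stability <- cluster_stability(D_sel, labels, linkage = linkage, M = M,
                                   seed = seed,
                                   .gap_index = length(grid) + j_sel)
  }

  structure(
    list(
      stats = stats_tbl,
      selection = selection,
      partition = partition,
      stability = stability,
      dendrograms = stats::setNames(purrr::map(per_gap, "Z"),
                                    format_duration(grid)),
      similarity = S_sel,
      distance = D_sel,
      seqs = pe_tbl(sl),
      config = list(g_grid = grid, match = match, mismatch = mismatch,
                    temporal = temporal, M = M, linkage = linkage,
                    k_min = k_min, k_max = k_max, mode = mode, seed = seed)
    ),
    class = "tnw_sweep"
  )
}

#' Automatic selection of the number of clusters and gap penalty
#'
#' Implements the modal-argmax rule: for every gap value and every
#' partition-comparison index, find the cluster number `q` with the highest
#' bootstrap mean; the selected `k` is the most frequent such argmax across
#' indices (and grid values). Ties between candidate `k` are broken by the
#' smaller standard deviation of the adjusted Rand index at the candidate,
#' then by the smaller `k`. The selected `g` is the grid value with the
#' highest average of the five index means at the chosen `k`.
#'
#' @param stats_tbl A tibble with columns `g`, `q`, `index`, `mean`, `sd`
#'   (the `stats` element of a [run_sweep()] result, or a
#'   [bootstrap_index_stats()] table augmented with a `g` column).
#' @return A list with elements `k`, `g` and `votes` (tibble of per-(g,
#'   index) argmax choices).
#' @export
select_k <- function(stats_tbl) {
  if (nrow(stats_tbl) == 0L) stop("empty statistics table", call. = FALSE)
  votes <- stats_tbl |>
    dplyr::group_by(.data$g, .data$index) |>
    dplyr::slice_max(.data$mean, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("g", "index", q_star = "q", mean_at_star = "mean")
  tally <- votes |> dplyr::count(.data$q_star, sort = TRUE)
  top <- tally |> dplyr::filter(.data$n == max(.data$n))
  if (nrow(top) == 1L) {
    k <- top$q_star[1L]
  } else {
    ar_sd <- stats_tbl |>
      dplyr::filter(.data$index == "adjusted_rand",
                    .data$q %in% top$q_star) |>
      dplyr::group_by(.data$q) |>
      dplyr::summarise(sd = min(.data$sd), .groups = "drop") |>
      dplyr::arrange(.data$sd, .data$q)
    k <- ar_sd$q[1L]
  }
  g_rank <- stats_tbl |>
    dplyr::filter(.data$q == k) |>
    dplyr::group_by(.data$g) |>
    dplyr::summarise(score = mean(.data$mean), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$g)
  list(k = as.integer(k), g = g_rank$g[1L], votes = votes)
}

#' @export
print.tnw_sweep <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<tnw_sweep> N = %d subjects, gap grid %s, M = %d, linkage = %s\n",
              nrow(x$seqs),
              paste(format_duration(cfg$g_grid), collapse = ", "),
              cfg$M, cfg$linkage))
  if (!is.null(x$selection)) {
    cat(sprintf("  selected k = %d at g = %g\n", x$selection$k, x$selection$g))
    cat("  cluster sizes: ",
        paste(table(x$partition$cluster), collapse = ", "), "\n", sep = "")
  } else {
    cat("  semi-automatic mode: inspect tidy(.) and dendrograms, then choose k and g\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-(g, q, index) bootstrap statistics of a sweep
#'
#' @param x A `tnw_sweep` object.
#' @param ... Unused.
#' @return The `stats` tibble: columns `g`, `q`, `index`, `median`, `mean`,
#'   `variance`, `sd`.
#' @export
#' @method tidy tnw_sweep
tidy.tnw_sweep <- function(x, ...) x$stats

#' One-row summary of a sweep
#'
#' @param x A `tnw_sweep` object.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `k`, `g`, `linkage`, `M`, `seed`, and the
#'   mean adjusted Rand at the selection (`NA` before a choice is made in
#'   semi-automatic mode).
#' @export
#' @method glance tnw_sweep
glance.tnw_sweep <- function(x, ...) {
  sel_k <- if (is.null(x$selection)) NA_integer_ else x$selection$k
  sel_g <- if (is.null(x$selection)) NA_real_ else x$selection$g
  ar <- NA_real_
  if (!is.null(x$selection)) {
    row <- dplyr::filter(x$stats, .data$g == sel_g, .data$q == sel_k,
                         .data$index == "adjusted_rand")
    if (nrow(row) == 1L) ar <- row$mean
  }
  tibble::tibble(
    n = nrow(x$seqs), k = sel_k, g = sel_g,
    linkage = x$config$linkage, M = x$config$M, seed = x$config$seed,
    mean_adjusted_rand = ar
  )
}

#' Plot bootstrap index means across cluster numbers
#'
#' One panel per partition-comparison index; the mean over bootstrap
#' replicates is drawn against the number of clusters `q`, one line per gap
#' penalty, with a ribbon of plus/minus one standard deviation.
#'
#' @param object A `tnw_sweep` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot tnw_sweep
autoplot.tnw_sweep <- function(object, ...) {
  df <- object$stats |>
    dplyr::mutate(g = factor(format_duration(.data$g),
                             levels = format_duration(object$config$g_grid)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$mean,
                                   colour = .data$g, group = .data$g)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd,
                                      fill = .data$g),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "number of clusters q", y = "bootstrap mean",
                  colour = "gap g", fill = "gap g") +
    ggplot2::theme_minimal()
}

#' Plot a per-cluster stability report
#'
#' Bars of the average Jaccard (`tau`), recovery rate (`gamma`) and Dice
#' (`eta`) per cluster, with one-standard-deviation error bars.
#'
#' @param object A `stability_report` from [cluster_stability()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot stability_report
autoplot.stability_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cluster),
                                   y = .data$average, fill = .data$measure)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$average - .data$sd, 0),
                   ymax = pmin(.data$average + .data$sd, 1)),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::labs(x = "cluster", y = "average over bootstrap replicates",
                  fill = "measure") +
    ggplot2::theme_minimal()
}
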