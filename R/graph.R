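#' Summarise a cluster of sequences as a transition graph
#'
#' Every consecutive event pair `(s_i, s_{i+1})` in every sequence of the
#' cluster contributes one transition `s_i -> s_{i+1}` with the observed
#' duration `t_{i+1}`. Edges carry the empirical switch probability (count
#' divided by the total number of transitions in the cluster, so the edge
#' probabilities sum to 1 over the whole graph) and the median of the
#' observed durations for that switch (even counts take the midpoint of the
#' two central values). The censoring symbol `"Z"`, when present, appears as
#' a terminal node. Sequences with a single event contain no transition and
#' are skipped with a message.
#'
#' @param cluster_sequences A sequence tibble, list of `pe_seq` objects, or
#'   character vector of PE strings — the members of one cluster.
#' @return A tibble of class `transition_graph` with one row per edge:
#'   `from`, `to`, `count`, `probability`, `median_time`, `shade` (grey
#'   level in `[0, 1]`, darker for more frequent switches: linear from 0.9
#'   as probability approaches 0 down to 0 at probability 1). The node set
#'   is stored in attribute `nodes`.
#' @examples
#' build_graph(c("0.A,1.B", "0.A,3.B", "0.A,5.C"))
#' @export
build_graph <- function(cluster_sequences) {
  sl <- seq_list(cluster_sequences)
  if (length(sl) == 0L) stop("empty cluster", call. = FALSE)
  short <- vapply(sl, length, integer(1L)) < 2L
  if (any(short)) {
    message(sprintf("skipping %d sequence(s) with no transition", sum(short)))
    sl <- sl[!short]
  }
  if (length(sl) == 0L) stop("no sequence in the cluster has a transition", call. = FALSE)
  trans <- purrr::map_dfr(sl, function(s) {
    n <- length(s$symbols)
    tibble::tibble(
      from = s$symbols[-n],
      to = s$symbols[-1L],
      time = s$durations[-1L]
    )
  })
  total <- nrow(trans)
  edges <- trans |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(
      count = dplyr::n(),
      median_time = stats::median(.data$time),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      probability = .data$count / total,
      shade = 0.9 * (1 - .data$probability)
    ) |>
    dplyr::relocate("probability", .after = "count") |>
    dplyr::arrange(.data$from, .data$to)
  nodes <- sort(unique(c(edges$from, edges$to)))
  structure(edges, class = c("transition_graph", class(edges)), nodes = nodes)
}

#' Convert a transition graph to an igraph object
#'
#' @param g A `transition_graph` from [build_graph()].
#' @return An [igraph::graph_from_data_frame()] directed graph with the edge
#'   attributes of the table.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "transition_graph"))
  igraph::graph_from_data_frame(tibble::as_tibble(g), directed = TRUE,
                                vertices = attr(g, "nodes"))
}

shade_hex <- function(shade) grDevices::gray(pmin(pmax(shade, 0), 1))

#' Export a transition graph
#'
#' Writes the graph as Graphviz DOT (edge colour encodes the switch
#' probability on a grey scale, edge label gives the median switch time),
#' GraphML (via igraph), or a plain CSV edge table `(from, to, count,
#' probability, median_time)` re-importable with [read_graph_csv()].
#'
#' @param g A `transition_graph`.
#' @param file Output path.
#' @param format `"dot"`, `"graphml"` or `"csv"`.
#' @return The path, invisibly.
#' @export
export_graph <- function(g, file, format = c("dot", "graphml", "csv")) {
  stopifnot(inherits(g, "transition_graph"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(
      tibble::as_tibble(g)[, c("from", "to", "count", "probability",
                               "median_time")],
      file, row.names = FALSE
    )
  } else if (format == "graphml") {
    igraph::write_graph(as_igraph(g), file, format = "graphml")
  } else {
    lines <- c(
      "digraph cluster {",
      "  rankdir=LR;",
      sprintf("  \"%s\";", attr(g, "nodes")),
      sprintf("  \"%s\" -> \"%s\" [label=\"%s\", color=\"%s\", penwidth=%s];",
              g$from, g$to, format_duration(g$median_time),
              shade_hex(g$shade), format_duration(0.5 + 2.5 * g$probability)),
      "}"
    )
    writeLines(lines, file)
  }
  invisible(file)
}

#' @rdname export_graph
#' @export
read_graph_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to", "count", "probability", "median_time")
                %in% names(df)))
  edges <- tibble::as_tibble(df) |>
    dplyr::mutate(shade = 0.9 * (1 - .data$probability)) |>
    dplyr::arrange(.data$from, .data$to)
  nodes <- sort(unique(c(edges$from, edges$to)))
  structure(edges, class = c("transition_graph", class(edges)), nodes = nodes)
}

#' Plot a transition graph
#'
#' Nodes are placed on a circle; directed edges are drawn with darkness
#' proportional to the switch probability and labelled with the median
#' switch time.
#'
#' @param object A `transition_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot transition_graph
autoplot.transition_graph <- function(object, ...) {
  nodes <- attr(object, "nodes")
  k <- length(nodes)
  ang <- seq(0, 2 * pi, length.out = k + 1L)[seq_len(k)]
  layout <- tibble::tibble(node = nodes, x = cos(ang), y = sin(ang))
  ed <- tibble::as_tibble(object) |>
    dplyr::left_join(layout, by = c(from = "node")) |>
    dplyr::left_join(layout, by = c(to = "node"), suffix = c("", "_to"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$x_to, yend = .data$y_to,
                   colour = .data$shade, linewidth = .data$probability),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "inches"),
                             type = "closed")
    ) +
    ggplot2::geom_label(
      data = ed,
      ggplot2::aes(x = (.data$x + .data$x_to) / 2,
                   y = (.data$y + .data$y_to) / 2,
                   label = format_duration(.data$median_time)),
      size = 3
    ) +
    ggplot2::geom_label(data = layout,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$node),
                        fontface = "bold") +
    ggplot2::scale_colour_gradient(low = "black", high = "grey90",
                                   limits = c(0, 0.9), guide = "none") +
    ggplot2::scale_linewidth(range = c(0.3, 2), guide = "none") +
    ggplot2::theme_void()
}
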