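#' Scoring scheme for temporal Needleman-Wunsch alignment
#'
#' The temporal Needleman-Wunsch (TNW) algorithm scores a global alignment of
#' two event sequences with a symbol match/mismatch score, a gap penalty `g`
#' for events aligned against nothing, and a temporal penalty that subtracts
#' `temporal * |t_x - t_y|` from every aligned event pair, where `t` is the
#' event's preceding duration. With `temporal = 0` the score reduces to the
#' classic Needleman-Wunsch score of the symbol strings.
#'
#' @param match Score of an aligned identical symbol pair (default 1).
#' @param mismatch Score of an aligned differing symbol pair (default -1.1).
#' @param gap Non-negative gap penalty `g` (default 0.7).
#' @param temporal Non-negative temporal penalty weight (default 0.25),
#'   in units of score per unit time difference.
#' @return A `scoring_scheme` list.
#' @examples
#' scoring_scheme()
#' scoring_scheme(gap = 1, temporal = 0)
#' @export
scoring_scheme <- function(match = 1, mismatch = -1.1, gap = 0.7,
                           temporal = 0.25) {
  stopifnot(is.numeric(match), is.numeric(mismatch), is.numeric(gap),
            is.numeric(temporal))
  if (gap < 0 || temporal < 0) {
    stop("`gap` and `temporal` must be non-negative", call. = FALSE)
  }
  if (match <= mismatch) {
    stop("`match` must exceed `mismatch`", call. = FALSE)
  }
  structure(
    list(match = match, mismatch = mismatch, gap = gap, temporal = temporal),
    class = "scoring_scheme"
  )
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("<scoring_scheme> match=%g mismatch=%g gap=%g temporal=%g\n",
              x$match, x$mismatch, x$gap, x$temporal))
  invisible(x)
}

as_pe <- function(x) {
  if (inherits(x, "pe_seq")) x else parse_pe(as.character(x))
}

# Dynamic-programming fill for the TNW recurrence:
#   H[0,0] = 0, H[i,0] = -i*g, H[0,j] = -j*g
#   H[i,j] = max( H[i-1,j-1] + s(x_i,y_j) - Tp*|t_xi - t_yj|,
#                 H[i-1,j] - g,  H[i,j-1] - g )
# Only substituted pairs pay the temporal term; gaps pay g alone.
tnw_matrix <- function(x, y, ss) {
  nx <- length(x$symbols); ny <- length(y$symbols)
  sub <- ifelse(outer(x$symbols, y$symbols, "=="), ss$match, ss$mismatch) -
    ss$temporal * abs(outer(x$durations, y$durations, "-"))
  H <- matrix(0, nx + 1L, ny + 1L)
  H[, 1L] <- -(0:nx) * ss$gap
  H[1L, ] <- -(0:ny) * ss$gap
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      H[i + 1L, j + 1L] <- max(H[i, j] + sub[i, j],
                               H[i, j + 1L] - ss$gap,
                               H[i + 1L, j] - ss$gap)
    }
  }
  list(H = H, sub = sub)
}

#' Temporal Needleman-Wunsch alignment of two PE sequences
#'
#' Computes the optimal global alignment score of two temporal event
#' sequences under the TNW recurrence, and (for `tnw_align()`) the aligned
#' event pairs by traceback. Ties during traceback prefer the diagonal move,
#' then the vertical (gap in `y`), then the horizontal, which makes the
#' reported alignment deterministic; the score is unaffected by tie-breaking.
#'
#' @param x,y `pe_seq` objects or PE-format strings.
#' @param ss A [scoring_scheme()].
#' @return `tnw_score()` returns the optimal score (a scalar).
#'   `tnw_align()` returns a `tnw_alignment` object: a list with the `score`
#'   and a tibble `pairs` with columns `x_pos`, `y_pos` (event indices, `NA`
#'   for a gap), `x_symbol`, `y_symbol`.
#' @examples
#' tnw_score("0.A,5.B", "0.A,5.B", scoring_scheme())
#' tnw_align("0.A,5.B", "0.B", scoring_scheme(gap = 0.7))
#' @export
tnw_score <- function(x, y, ss = scoring_scheme()) {
  x <- as_pe(x); y <- as_pe(y)
  H <- tnw_matrix(x, y, ss)$H
  H[length(x$symbols) + 1L, length(y$symbols) + 1L]
}

#' @rdname tnw_score
#' @export
tnw_align <- function(x, y, ss = scoring_scheme()) {
  x <- as_pe(x); y <- as_pe(y)
  dp <- tnw_matrix(x, y, ss)
  H <- dp$H; sub <- dp$sub
  i <- length(x$symbols); j <- length(y$symbols)
  xp <- integer(0); yp <- integer(0)
  eps <- 1e-9
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        abs(H[i + 1L, j + 1L] - (H[i, j] + sub[i, j])) < eps) {
      xp <- c(i, xp); yp <- c(j, yp); i <- i - 1L; j <- j - 1L
    } else if (i > 0L &&
               abs(H[i + 1L, j + 1L] - (H[i, j + 1L] - ss$gap)) < eps) {
      xp <- c(i, xp); yp <- c(NA_integer_, yp); i <- i - 1L
    } else {
      xp <- c(NA_integer_, xp); yp <- c(j, yp); j <- j - 1L
    }
  }
  pairs <- tibble::tibble(
    x_pos = xp, y_pos = yp,
    x_symbol = ifelse(is.na(xp), "-", x$symbols[replace(xp, is.na(xp), 1L)]),
    y_symbol = ifelse(is.na(yp), "-", y$symbols[replace(yp, is.na(yp), 1L)])
  )
  structure(
    list(score = H[nrow(H), ncol(H)], pairs = pairs,
         x = x, y = y, scheme = ss),
    class = "tnw_alignment"
  )
}

#' @export
print.tnw_alignment <- function(x, ...) {
  cat(sprintf("<tnw_alignment> score = %g\n", x$score))
  cat("  x: ", paste(x$pairs$x_symbol, collapse = " "), "\n")
  cat("  y: ", paste(x$pairs$y_symbol, collapse = " "), "\n")
  invisible(x)
}

seq_list <- function(seqs) {
  if (is.data.frame(seqs)) {
    stopifnot("seq" %in% names(seqs))
    out <- seqs$seq
    names(out) <- seqs$patient_id
    out
  } else {
    out <- lapply(seqs, as_pe)
    nm <- vapply(out, function(s) as.character(s$patient_id), character(1L))
    if (anyNA(nm) || any(!nzchar(nm))) nm <- as.character(seq_along(out))
    names(out) <- make.unique(nm)
    out
  }
}

#' All-pairs TNW similarity matrix
#'
#' Aligns every pair of sequences and collects the scores into a symmetric
#' N x N matrix. Only the N(N-1)/2 upper-triangle alignments are computed;
#' the diagonal is left as `NA` (self-similarities play no role downstream
#' and are never computed).
#'
#' @param seqs A sequence tibble (with a `seq` list column, as produced by
#'   [panel_to_pe()] / [pe_tbl()]) or a list of `pe_seq` objects or PE
#'   strings.
#' @param ss A [scoring_scheme()].
#' @return A symmetric numeric matrix of class `tnw_sim` with the subject IDs
#'   as dimnames and `NA` on the diagonal.
#' @examples
#' s <- similarity_matrix(list("0.A,5.B", "0.A,5.B", "0.B"), scoring_scheme())
#' @export
similarity_matrix <- function(seqs, ss = scoring_scheme()) {
  sl <- seq_list(seqs)
  n <- length(sl)
  if (n < 2L) stop("need at least two sequences", call. = FALSE)
  S <- matrix(NA_real_, n, n, dimnames = list(names(sl), names(sl)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      S[i, j] <- S[j, i] <- tnw_score(sl[[i]], sl[[j]], ss)
    }
  }
  structure(S, class = c("tnw_sim", "matrix"))
}

#' Convert a similarity matrix to a distance matrix
#'
#' Distances are the negated similarities shifted by the maximum off-diagonal
#' similarity `a = max_{i<j} S[i,j]`, i.e. `D = a - S` off the diagonal and 0
#' on it, so all entries are non-negative and the most similar pair sits at
#' distance exactly 0.
#'
#' @param S A similarity matrix from [similarity_matrix()] (or any symmetric
#'   numeric matrix; the diagonal is ignored).
#' @return A symmetric non-negative matrix of class `tnw_dist` with zero
#'   diagonal and attribute `shift` holding `a`.
#' @examples
#' S <- similarity_matrix(list("0.A", "0.A", "0.B"))
#' D <- to_distance(S)
#' attr(D, "shift")
#' @export
to_distance <- function(S) {
  S <- unclass(S)
  stopifnot(is.matrix(S), nrow(S) == ncol(S), nrow(S) >= 2L)
  off <- S[upper.tri(S)]
  a <- max(off)
  D <- a - S
  diag(D) <- 0
  structure(D, shift = a, class = c("tnw_dist", "matrix"))
}
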