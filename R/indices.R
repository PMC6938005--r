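#' Partition-comparison indices
#'
#' Compares two partitions of the same elements through the classical pair
#' counts: `a` pairs together in both, `b` together in `P` only, `c` together
#' in `Q` only, `d` apart in both. Returns five indices:
#'
#' * `rand` = (a + d) / (a + b + c + d)
#' * `adjusted_rand` — the Hubert-Arabie chance-corrected Rand index
#' * `fowlkes_mallows` = a / sqrt((a + b)(a + c))
#' * `jaccard` = a / (a + b + c)
#' * `adjusted_wallace` — the chance-corrected Wallace coefficient
#'   W = a / (a + b), directional from `p` to `q` (the expected Wallace under
#'   independence is the probability that a random pair is together in `q`)
#'
#' Degenerate denominators follow bounded conventions: Jaccard and
#' Fowlkes-Mallows are 0 when their denominator is 0; the adjusted indices
#' are 1 when their denominator is 0 and the partitions are identical, else
#' 0.
#'
#' @param p,q Integer (or factor) label vectors of equal length.
#' @return A tibble with one row and columns `rand`, `adjusted_rand`,
#'   `fowlkes_mallows`, `jaccard`, `adjusted_wallace`.
#' @examples
#' compare_partitions(c(1, 1, 2, 2), c(1, 1, 2, 2))
#' compare_partitions(c(1, 1, 2, 2), c(1, 2, 1, 2))
#' @export
compare_partitions <- function(p, q) {
  if (length(p) != length(q)) {
    stop("partitions must label the same elements", call. = FALSE)
  }
  n <- length(p)
  if (n < 2L) stop("need at least two elements", call. = FALSE)
  ct <- table(p, q)
  tot <- choose(n, 2)
  a <- sum(choose(ct, 2))
  rows <- sum(choose(rowSums(ct), 2))   # together in p
  cols <- sum(choose(colSums(ct), 2))   # together in q
  b <- rows - a
  c_ <- cols - a
  d <- tot - rows - cols + a

  identical_parts <- (b == 0 && c_ == 0)
  rand <- (a + d) / tot
  jaccard <- if (a + b + c_ == 0) 0 else a / (a + b + c_)
  fm <- if (rows == 0 || cols == 0) 0 else a / sqrt(rows * cols)

  exp_a <- rows * cols / tot
  ar_den <- (rows + cols) / 2 - exp_a
  ar <- if (abs(ar_den) < .Machine$double.eps * tot) {
    if (identical_parts) 1 else 0
  } else {
    (a - exp_a) / ar_den
  }

  w_exp <- cols / tot                   # P(random pair together in q)
  aw <- if (rows == 0 || 1 - w_exp <= .Machine$double.eps) {
    if (identical_parts) 1 else 0
  } else {
    (a / rows - w_exp) / (1 - w_exp)
  }

  tibble::tibble(
    rand = rand, adjusted_rand = ar, fowlkes_mallows = fm,
    jaccard = jaccard, adjusted_wallace = aw
  )
}

index_names <- c("rand", "adjusted_rand", "fowlkes_mallows", "jaccard",
                 "adjusted_wallace")
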