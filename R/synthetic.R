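#' Continuous-time Markov chain specification
#'
#' Describes the generator used to simulate temporal event sequences: an
#' embedded jump chain (row-stochastic matrix with zero diagonal) over a
#' finite symbol alphabet, exponential sojourn times with a per-state rate,
#' an initial state distribution, and a law for the number of events per
#' sequence.
#'
#' @param alphabet Character vector of state symbols (must not include the
#'   reserved censoring symbol `"Z"`).
#' @param jump_matrix Square row-stochastic matrix (rows sum to 1, zero
#'   diagonal): `jump_matrix[i, j]` is the probability of jumping from state
#'   `i` to state `j`.
#' @param holding_rates Positive rate per state; sojourn in state `i` is
#'   Exponential(`holding_rates[i]`), i.e. mean `1 / holding_rates[i]`.
#' @param initial Initial state distribution (default uniform).
#' @param n_events Either a single event count or a length-2 vector
#'   `c(min, max)` from which each sequence's count is drawn uniformly.
#' @param censor If `TRUE`, sequences are terminated with the censoring
#'   symbol `"Z"` (one extra event with an exponential duration from the last
#'   state).
#' @return A `ctmc_spec` list.
#' @examples
#' ctmc_spec(c("A", "B"), matrix(c(0, 1, 1, 0), 2, 2), holding_rates = 1)
#' @export
ctmc_spec <- function(alphabet, jump_matrix, holding_rates,
                      initial = NULL, n_events = c(3L, 6L), censor = FALSE) {
  k <- length(alphabet)
  stopifnot(k >= 2L, is.matrix(jump_matrix), nrow(jump_matrix) == k,
            ncol(jump_matrix) == k)
  if ("Z" %in% alphabet) {
    stop("'Z' is reserved for censoring and cannot be a CTMC state", call. = FALSE)
  }
  if (any(diag(jump_matrix) != 0)) {
    stop("jump_matrix must have a zero diagonal (embedded chain)", call. = FALSE)
  }
  if (any(abs(rowSums(jump_matrix) - 1) > 1e-8) || any(jump_matrix < 0)) {
    stop("jump_matrix rows must be non-negative and sum to 1", call. = FALSE)
  }
  holding_rates <- rep_len(as.numeric(holding_rates), k)
  if (any(holding_rates <= 0)) stop("holding_rates must be positive", call. = FALSE)
  initial <- initial %||% rep(1 / k, k)
  if (length(initial) != k || any(initial < 0) || abs(sum(initial) - 1) > 1e-8) {
    stop("initial must be a probability vector over the alphabet", call. = FALSE)
  }
  n_events <- as.integer(n_events)
  if (!length(n_events) %in% 1:2 || any(n_events < 1L)) {
    stop("n_events must be a positive count or a c(min, max) range", call. = FALSE)
  }
  structure(
    list(alphabet = alphabet, jump_matrix = jump_matrix,
         holding_rates = holding_rates, initial = initial,
         n_events = n_events, censor = censor),
    class = "ctmc_spec"
  )
}

#' Simulate one PE sequence from a CTMC
#'
#' The first event is drawn from the initial distribution with duration 0;
#' each subsequent event draws its duration from the current state's
#' exponential sojourn law and its symbol from the jump matrix row. Uses the
#' caller's RNG stream (seed with [set.seed()] or let a higher-level driver
#' manage seeding).
#'
#' @param spec A [ctmc_spec()].
#' @param patient_id Identifier for the emitted sequence.
#' @return A `pe_seq` object.
#' @examples
#' set.seed(1)
#' sample_ctmc_sequence(ctmc_spec(c("A", "B"), matrix(c(0, 1, 1, 0), 2, 2), 1))
#' @export
sample_ctmc_sequence <- function(spec, patient_id = NA_character_) {
  stopifnot(inherits(spec, "ctmc_spec"))
  k <- length(spec$alphabet)
  n <- if (length(spec$n_events) == 2L) {
    spec$n_events[1L] + sample.int(spec$n_events[2L] - spec$n_events[1L] + 1L, 1L) - 1L
  } else {
    spec$n_events
  }
  states <- integer(n)
  durations <- numeric(n)
  states[1L] <- sample.int(k, 1L, prob = spec$initial)
  for (i in seq_len(n - 1L)) {
    durations[i + 1L] <- stats::rexp(1L, rate = spec$holding_rates[states[i]])
    states[i + 1L] <- sample.int(k, 1L, prob = spec$jump_matrix[states[i], ])
  }
  symbols <- spec$alphabet[states]
  if (spec$censor) {
    durations <- c(durations, stats::rexp(1L, rate = spec$holding_rates[states[n]]))
    symbols <- c(symbols, "Z")
  }
  pe_seq(durations, symbols, patient_id)
}

#' Default pair of well-separated CTMC specifications
#'
#' The packaged two-cluster benchmark: both chains live on the alphabet
#' `{A, B, C, D}` and event counts uniform on 3..6, but cluster 1 favours
#' A–B jumps (probability 0.8, starting in A or B) with mean sojourn 2.0
#' time units, while cluster 2 favours C–D jumps (probability 0.8, starting
#' in C or D) with mean sojourn 6.0. The two groups thus differ both in
#' symbol usage and in time scale, which is what "well separated" means
#' here.
#'
#' @return A list of two [ctmc_spec()] objects.
#' @export
ctmc_two_cluster_specs <- function() {
  ab <- c("A", "B", "C", "D")
  jump1 <- matrix(c(
    0.0, 0.8, 0.1, 0.1,
    0.8, 0.0, 0.1, 0.1,
    0.4, 0.4, 0.0, 0.2,
    0.4, 0.4, 0.2, 0.0
  ), 4, 4, byrow = TRUE, dimnames = list(ab, ab))
  jump2 <- jump1[c(3, 4, 1, 2), c(3, 4, 1, 2)]
  dimnames(jump2) <- list(ab, ab)
  list(
    ctmc_spec(ab, jump1, holding_rates = 1 / 2,
              initial = c(0.5, 0.5, 0, 0), n_events = c(3L, 6L)),
    ctmc_spec(ab, jump2, holding_rates = 1 / 6,
              initial = c(0, 0, 0.5, 0.5), n_events = c(3L, 6L))
  )
}

#' Generate a labelled two-cluster synthetic dataset
#'
#' Draws `n_per_cluster` sequences from each of two CTMC specifications,
#' shuffles them, and records the generating cluster as the ground-truth
#' label.
#'
#' @param spec1,spec2 [ctmc_spec()] objects (default: the well-separated
#'   pair of [ctmc_two_cluster_specs()]).
#' @param n_per_cluster Sequences per cluster (default 20, minimum 2).
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of it.
#' @return A sequence tibble (as from [pe_tbl()]) with an extra integer
#'   column `label` in `{1, 2}` giving the generating cluster.
#' @examples
#' make_two_cluster_dataset(n_per_cluster = 3, seed = 1)
#' @export
make_two_cluster_dataset <- function(spec1 = NULL, spec2 = NULL,
                                     n_per_cluster = 20, seed = 42) {
  if (is.null(spec1) || is.null(spec2)) {
    defaults <- ctmc_two_cluster_specs()
    spec1 <- spec1 %||% defaults[[1L]]
    spec2 <- spec2 %||% defaults[[2L]]
  }
  if (n_per_cluster < 2L) stop("n_per_cluster must be >= 2", call. = FALSE)
  local_seed(derive_seed(seed, 0, 0), {
    labels <- rep(1:2, each = n_per_cluster)
    seqs <- lapply(seq_along(labels), function(i) {
      spec <- if (labels[i] == 1L) spec1 else spec2
      sample_ctmc_sequence(spec, sprintf("S%02d", i))
    })
    ord <- sample.int(length(seqs))
    out <- pe_tbl(seqs[ord])
    out$label <- labels[ord]
    out
  })
}
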