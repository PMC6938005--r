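# Exhaustive enumeration of all global alignments (gaps included): the
# independent oracle for the TNW dynamic program. Practical for sequence
# lengths up to ~5.
enum_tnw_score <- function(x, y, ss) {
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      sc <- (if (x$symbols[i] == y$symbols[j]) ss$match else ss$mismatch) -
        ss$temporal * abs(x$durations[i] - y$durations[j])
      best <- max(best, rec(i - 1L, j - 1L) + sc)
    }
    if (i > 0L) best <- max(best, rec(i - 1L, j) - ss$gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) - ss$gap)
    best
  }
  rec(length(x$symbols), length(y$symbols))
}

# Classic Needleman-Wunsch on the symbol strings only (no temporal term);
# written independently of the package's DP code.
nw_score <- function(xs, ys, match, mismatch, gap) {
  nx <- length(xs); ny <- length(ys)
  prev <- -(0:ny) * gap
  for (i in seq_len(nx)) {
    cur <- numeric(ny + 1L)
    cur[1L] <- -i * gap
    for (j in seq_len(ny)) {
      sc <- if (xs[i] == ys[j]) match else mismatch
      cur[j + 1L] <- max(prev[j] + sc, prev[j + 1L] - gap, cur[j] - gap)
    }
    prev <- cur
  }
  prev[ny + 1L]
}

# Brute-force O(N^2) pair-counting oracle for the partition indices.
brute_indices <- function(p, q) {
  n <- length(p)
  a <- b <- c_ <- d <- 0
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      sp <- p[i] == p[j]; sq <- q[i] == q[j]
      if (sp && sq) a <- a + 1
      else if (sp && !sq) b <- b + 1
      else if (!sp && sq) c_ <- c_ + 1
      else d <- d + 1
    }
  }
  tot <- a + b + c_ + d
  exp_a <- (a + b) * (a + c_) / tot
  ar_den <- ((a + b) + (a + c_)) / 2 - exp_a
  w_exp <- (a + c_) / tot
  list(
    rand = (a + d) / tot,
    adjusted_rand = if (abs(ar_den) < 1e-12) {
      if (b == 0 && c_ == 0) 1 else 0
    } else (a - exp_a) / ar_den,
    fowlkes_mallows = if ((a + b) == 0 || (a + c_) == 0) 0 else
      a / sqrt((a + b) * (a + c_)),
    jaccard = if (a + b + c_ == 0) 0 else a / (a + b + c_),
    adjusted_wallace = if ((a + b) == 0 || 1 - w_exp <= 1e-12) {
      if (b == 0 && c_ == 0) 1 else 0
    } else (a / (a + b) - w_exp) / (1 - w_exp)
  )
}

random_pe <- function(max_len = 4L, alphabet = c("A", "B", "C"),
                      max_dur = 5L) {
  n <- sample.int(max_len, 1L)
  pe_seq(c(0, sample(0:max_dur, n - 1L, replace = TRUE)),
         sample(alphabet, n, replace = TRUE))
}

random_scheme <- function() {
  scoring_scheme(match = runif(1, 0.5, 2), mismatch = runif(1, -2, 0),
                 gap = runif(1, 0, 2), temporal = runif(1, 0, 1))
}

# Two tight groups far apart: within-group distances are all smaller than
# every between-group distance.
two_block_distance <- function(n1 = 5L, n2 = 5L, within = 1, between = 10) {
  n <- n1 + n2
  D <- matrix(between, n, n)
  D[seq_len(n1), seq_len(n1)] <- within
  D[n1 + seq_len(n2), n1 + seq_len(n2)] <- within
  diag(D) <- 0
  D
}
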