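test_that("tnw_score reproduces hand-checked alignments", {
  ss <- scoring_scheme(match = 1, mismatch = -1.1, gap = 0.7, temporal = 0.25)
  # identical single events: a match with zero time difference
  expect_equal(tnw_score("0.A", "0.A", ss), 1)
  # mismatch (-1.1) beats two gaps (-1.4)
  expect_equal(tnw_score("0.A", "0.B", ss), -1.1)
  # self-alignment of a two-event sequence: two exact matches
  expect_equal(tnw_score("0.A,5.B", "0.A,5.B", ss), 2)
  # aligned pair pays the temporal penalty on the duration difference
  expect_equal(tnw_score("0.A,5.B", "0.A,1.B", ss), 2 - 0.25 * 4)
})

test_that("tnw_score equals the exhaustive-enumeration oracle on random pairs", {
  set.seed(101)
  for (r in 1:150) {
    x <- random_pe(); y <- random_pe()
    ss <- random_scheme()
    expect_equal(tnw_score(x, y, ss), enum_tnw_score(x, y, ss),
                 tolerance = 1e-12)
  }
})

test_that("with zero temporal penalty TNW reduces to classic Needleman-Wunsch", {
  set.seed(102)
  for (r in 1:60) {
    x <- random_pe(max_len = 6L, max_dur = 50L)
    y <- random_pe(max_len = 6L, max_dur = 50L)
    ss <- scoring_scheme(match = runif(1, 0.5, 2), mismatch = runif(1, -2, 0),
                         gap = runif(1, 0, 2), temporal = 0)
    expect_equal(tnw_score(x, y, ss),
                 nw_score(x$symbols, y$symbols, ss$match, ss$mismatch, ss$gap),
                 tolerance = 1e-9)
  }
})

test_that("tnw_score is symmetric and maximal at self-alignment", {
  set.seed(103)
  for (r in 1:40) {
    x <- random_pe(); y <- random_pe()
    ss <- random_scheme()
    expect_equal(tnw_score(x, y, ss), tnw_score(y, x, ss), tolerance = 1e-12)
    expect_gte(tnw_score(x, x, ss), tnw_score(x, y, ss) - 1e-12)
  }
})

test_that("increasing an aligned pair's time difference never raises the score", {
  ss <- scoring_scheme(gap = 0.7, temporal = 0.25)
  base <- tnw_score("0.A,5.B", "0.A,5.B", ss)
  worse <- vapply(c(6, 8, 12, 20),
                  function(t) tnw_score(parse_pe(sprintf("0.A,%g.B", t)),
                                        parse_pe("0.A,5.B"), ss),
                  numeric(1))
  expect_true(all(diff(c(base, worse)) <= 1e-12))
})

test_that("traceback recovers both sequences and matches the score", {
  set.seed(104)
  for (r in 1:25) {
    x <- random_pe(); y <- random_pe()
    ss <- random_scheme()
    al <- tnw_align(x, y, ss)
    expect_equal(al$score, tnw_score(x, y, ss), tolerance = 1e-12)
    expect_equal(al$pairs$x_pos[!is.na(al$pairs$x_pos)],
                 seq_along(x$symbols))
    expect_equal(al$pairs$y_pos[!is.na(al$pairs$y_pos)],
                 seq_along(y$symbols))
  }
})

test_that("censoring symbol Z aligns as an ordinary symbol", {
  ss <- scoring_scheme(gap = 0.7, temporal = 0.25)
  expect_equal(tnw_score("0.A,2.Z", "0.A,2.Z", ss), 2)
})

test_that("similarity_matrix is symmetric with an uncomputed diagonal", {
  S <- similarity_matrix(list("0.A", "0.B", "0.A"), scoring_scheme())
  expect_true(all(is.na(diag(unclass(S)))))
  expect_equal(unclass(S)[1, 3], 1)
  expect_equal(unclass(S)[1, 2], -1.1)
  expect_equal(unclass(S)[2, 3], -1.1)
  expect_equal(unclass(S), t(unclass(S)))
  expect_error(similarity_matrix(list("0.A")), "two sequences")

  two <- similarity_matrix(list("0.A,5.B", "0.A,5.B"))
  expect_equal(unclass(two)[1, 2], 2)
})

test_that("to_distance shifts by the maximum off-diagonal similarity", {
  S <- matrix(c(NA, 2, 1, 2, NA, 0, 1, 0, NA), 3, 3)
  D <- to_distance(S)
  expect_equal(attr(D, "shift"), 2)
  expect_equal(unclass(D)[upper.tri(D)], c(0, 1, 2))
  expect_equal(diag(unclass(D)), rep(0, 3))
})

test_that("distance matrices are symmetric, non-negative, zero-diagonal with min 0", {
  set.seed(105)
  for (r in 1:20) {
    n <- sample(3:10, 1)
    S <- matrix(NA_real_, n, n)
    vals <- rnorm(n * (n - 1) / 2, sd = 5)
    S[upper.tri(S)] <- vals
    S[lower.tri(S)] <- t(S)[lower.tri(S)]
    D <- unclass(to_distance(S))
    expect_equal(D, t(D))
    expect_true(all(D >= 0))
    expect_equal(diag(D), rep(0, n))
    expect_equal(min(D[upper.tri(D)]), 0)
  }
})
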