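test_that("ctmc_spec validates its parameters", {
  J <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_s3_class(ctmc_spec(c("A", "B"), J, 1), "ctmc_spec")
  expect_error(ctmc_spec(c("A", "Z"), J, 1), "reserved")
  expect_error(ctmc_spec(c("A", "B"), matrix(0.5, 2, 2), 1), "diagonal")
  expect_error(ctmc_spec(c("A", "B"), matrix(c(0, 1, 0.5, 0), 2, 2), 1),
               "sum to 1")
  expect_error(ctmc_spec(c("A", "B"), J, -1), "positive")
  expect_error(ctmc_spec(c("A", "B"), J, 1, initial = c(0.7, 0.7)),
               "probability vector")
})

test_that("a deterministic embedded chain alternates its two states", {
  spec <- ctmc_spec(c("A", "B"), matrix(c(0, 1, 1, 0), 2, 2),
                    holding_rates = 1, n_events = 3L)
  for (seed in 1:5) {
    set.seed(seed)
    s <- sample_ctmc_sequence(spec)
    expect_true(identical(s$symbols, c("A", "B", "A")) ||
                  identical(s$symbols, c("B", "A", "B")))
    expect_equal(s$durations[1], 0)
  }
})

test_that("sojourn durations follow the exponential holding law", {
  spec <- ctmc_spec(c("A", "B"), matrix(c(0, 1, 1, 0), 2, 2),
                    holding_rates = 1, n_events = 2L)
  set.seed(77)
  durs <- replicate(10000, sample_ctmc_sequence(spec)$durations[2])
  # Exponential(1): mean 1, se 1/sqrt(1e4) = 0.01; allow 3 standard errors
  expect_lt(abs(mean(durs) - 1), 0.03)
})

test_that("empirical transition frequencies converge to the jump matrix rows", {
  J <- matrix(c(0, 0.8, 0.2,
                0.3, 0, 0.7,
                0.5, 0.5, 0), 3, 3, byrow = TRUE)
  spec <- ctmc_spec(c("A", "B", "C"), J, holding_rates = 1, n_events = 2L,
                    initial = c(1, 0, 0))
  set.seed(78)
  to <- replicate(10000, sample_ctmc_sequence(spec)$symbols[2])
  p_hat <- mean(to == "B")
  se <- sqrt(0.8 * 0.2 / 10000)
  expect_lt(abs(p_hat - 0.8), 3 * se)
})

test_that("sampling is deterministic given the RNG state", {
  spec <- ctmc_two_cluster_specs()[[1]]
  set.seed(5); a <- sample_ctmc_sequence(spec)
  set.seed(5); b <- sample_ctmc_sequence(spec)
  expect_identical(a, b)
})

test_that("emitted sequences satisfy the PE invariants and round-trip", {
  specs <- ctmc_two_cluster_specs()
  set.seed(9)
  for (r in 1:50) {
    s <- sample_ctmc_sequence(specs[[1 + r %% 2]])
    expect_gte(length(s), 3L)
    expect_lte(length(s), 6L)
    expect_equal(s$durations[1], 0)
    expect_true(all(s$durations >= 0))
    back <- parse_pe(format_pe(s))
    expect_equal(back$symbols, s$symbols)
    # durations survive the 6-significant-digit rendering
    expect_equal(back$durations, s$durations, tolerance = 1e-5)
  }
})

test_that("make_two_cluster_dataset labels and counts line up", {
  ds <- make_two_cluster_dataset(n_per_cluster = 10, seed = 3)
  expect_equal(nrow(ds), 20L)
  expect_equal(unname(table(ds$label)), c(10L, 10L), ignore_attr = TRUE)
  expect_equal(anyDuplicated(ds$patient_id), 0L)
  # deterministic in the seed, independent of the caller's RNG
  set.seed(999)
  ds2 <- make_two_cluster_dataset(n_per_cluster = 10, seed = 3)
  expect_identical(ds$pe, ds2$pe)
  expect_error(make_two_cluster_dataset(n_per_cluster = 1), ">= 2")
})

test_that("the default specs separate symbol usage between clusters", {
  ds <- make_two_cluster_dataset(n_per_cluster = 30, seed = 8)
  frac_ab <- vapply(ds$seq, function(s) mean(s$symbols %in% c("A", "B")),
                    numeric(1))
  expect_gt(mean(frac_ab[ds$label == 1]), 0.7)
  expect_lt(mean(frac_ab[ds$label == 2]), 0.3)
})
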