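test_that("parse_pe reads the PE grammar and rejects malformed input", {
  s <- parse_pe("0.A,5.B")
  expect_equal(s$durations, c(0, 5))
  expect_equal(s$symbols, c("A", "B"))

  expect_equal(parse_pe("0.A")$symbols, "A")

  s <- parse_pe("0.A,3.B,2.Z")
  expect_equal(s$durations, c(0, 3, 2))
  expect_equal(s$symbols, c("A", "B", "Z"))

  expect_error(parse_pe("0.A,,5.B"), "malformed")
  expect_error(parse_pe("A,5.B"), "malformed")
  expect_error(parse_pe("1.A,5.B"), "0\\.")
  expect_error(parse_pe("0.A,2.Z,5.B"), "non-final")
  expect_error(parse_pe("0.A,2.Z,5.Z"), "non-final|once")
})

test_that("format_pe renders canonically and inverts parse_pe", {
  expect_equal(format_pe(pe_seq(c(0, 5), c("A", "B"))), "0.A,5.B")
  expect_equal(format_pe(pe_seq(0, "A")), "0.A")
  expect_equal(format_pe(pe_seq(c(0, 2.5), c("A", "Z"))), "0.A,2.5.Z")
})

test_that("parse_pe . format_pe is the identity on random sequences", {
  set.seed(11)
  for (r in 1:100) {
    n <- sample(1:8, 1)
    durs <- c(0, round(runif(n - 1, 0, 40), sample(0:3, 1)))
    syms <- sample(LETTERS[1:8], n, replace = TRUE)
    s <- pe_seq(durs, syms, paste0("P", r))
    s2 <- parse_pe(format_pe(s), paste0("P", r))
    expect_equal(s2$durations, s$durations)
    expect_equal(s2$symbols, s$symbols)
  }
})

test_that("pe_seq enforces its invariants", {
  expect_error(pe_seq(numeric(0), character(0)), "at least one")
  expect_error(pe_seq(c(1, 2), c("A", "B")), "duration 0")
  expect_error(pe_seq(c(0, -1), c("A", "B")), "non-negative")
  expect_error(pe_seq(c(0, 1), c("A.B", "C")), "','")
  expect_error(pe_seq(c(0, 1, 2), c("A", "Z", "B")), "final")
})

test_that("panel_to_pe handles numeric and date time modes", {
  dates <- data.frame(
    id = c("P1", "P1"), event = c("A", "B"),
    time = as.Date(c("2020-01-01", "2020-01-11"))
  )
  out <- panel_to_pe(dates)
  expect_equal(out$pe, "0.A,10.B")

  nums <- data.frame(id = c("P2", "P2"), event = c("A", "B"), time = c(0, 5))
  expect_equal(panel_to_pe(nums)$pe, "0.A,5.B")

  single <- data.frame(id = "P3", event = "A", time = 7)
  expect_equal(panel_to_pe(single)$pe, "0.A")

  iso <- data.frame(id = c("P1", "P1"), event = c("A", "B"),
                    time = c("2020-01-01", "2020-01-11"))
  expect_equal(panel_to_pe(iso)$pe, "0.A,10.B")
})

test_that("panel_to_pe is invariant to row order and covers each patient once", {
  df <- data.frame(
    id = c("P2", "P1", "P1", "P2", "P1"),
    event = c("A", "A", "B", "B", "C"),
    time = c(0, 0, 3, 4, 9)
  )
  out <- panel_to_pe(df)
  shuffled <- panel_to_pe(df[c(4, 1, 5, 3, 2), ])
  expect_equal(out, shuffled)
  expect_equal(nrow(out), 2L)
  expect_setequal(out$patient_id, c("P1", "P2"))
  expect_equal(out$pe[out$patient_id == "P1"], "0.A,3.B,6.C")
})

test_that("consecutive identical symbols collapse into one state", {
  df <- data.frame(
    id = rep("P1", 4), event = c("A", "A", "B", "B"), time = c(0, 2, 5, 9)
  )
  expect_equal(panel_to_pe(df)$pe, "0.A,5.B")
  expect_equal(panel_to_pe(df, collapse_repeats = FALSE)$pe, "0.A,2.A,3.B,4.B")
})

test_that("censoring appends Z with the time spent in the final state", {
  df <- data.frame(
    id = rep("P1", 3), event = c("A", "B", "B"), time = c(0, 4, 10)
  )
  expect_equal(panel_to_pe(df, censor = TRUE)$pe, "0.A,4.B,6.Z")
  # final state seen only once: censored at duration 0
  df2 <- data.frame(id = c("P1", "P1"), event = c("A", "B"), time = c(0, 4))
  expect_equal(panel_to_pe(df2, censor = TRUE)$pe, "0.A,4.B,0.Z")
})

test_that("tied times deduplicate identical symbols and reject conflicts", {
  dup <- data.frame(id = c("P1", "P1", "P1"), event = c("A", "A", "B"),
                    time = c(0, 0, 5))
  expect_equal(panel_to_pe(dup)$pe, "0.A,5.B")
  conflict <- data.frame(id = c("P1", "P1"), event = c("A", "B"), time = c(0, 0))
  expect_error(panel_to_pe(conflict), "P1")
})

test_that("PE files round-trip through write_pe and read_pe", {
  tbl <- pe_tbl(list(pe_seq(c(0, 5), c("A", "B"), "P1"),
                     pe_seq(c(0, 2.5), c("A", "Z"), "P2")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pe(tbl, f)
  back <- read_pe(f)
  expect_equal(back$patient_id, tbl$patient_id)
  expect_equal(back$pe, tbl$pe)
})
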