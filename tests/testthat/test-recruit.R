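ranked_fixture <- function(ids, scores)
  data.frame(read_id = ids, bitscore = scores, stringsAsFactors = FALSE)

test_that("the five selection modes follow their definitions", {
  rk <- ranked_fixture(paste0("r", 1:100), seq(200, 2, by = -2))
  expect_equal(select_reads(rk, selection_policy("all")), rk$read_id)
  expect_equal(select_reads(rk, selection_policy("bitscore",
                                                 bitscore_min = 150)),
               rk$read_id[rk$bitscore >= 150])
  # increment 10, cycle 3 -> top 30
  expect_equal(select_reads(rk, selection_policy("increment",
                                                 increment = 10), cycle = 3),
               rk$read_id[1:30])
  expect_equal(select_reads(rk, selection_policy("manual",
                                                 manual_counts = c(5, 12)),
                            cycle = 2),
               rk$read_id[1:12])
})

test_that("population mode extends by bitscore-tie groups to cover the previous cycle", {
  rk <- ranked_fixture(c("r3", "r1", "r4", "r2", "r5"),
                       c(90, 80, 70, 60, 50))
  got <- select_reads(rk, selection_policy("population"), cycle = 2,
                      previous_ids = c("r1", "r2"))
  expect_equal(got, c("r3", "r1", "r4", "r2"))
  # whole tie groups come in together
  rk2 <- ranked_fixture(c("a", "b", "c", "d"), c(90, 80, 80, 80))
  expect_equal(select_reads(rk2, selection_policy("population"), cycle = 2,
                            previous_ids = "b"),
               c("a", "b", "c", "d"))
  # vanished previous reads are ignored with a warning
  expect_warning(
    got3 <- select_reads(rk, selection_policy("population"), cycle = 2,
                         previous_ids = c("r1", "gone")),
    "no longer ranked")
  expect_equal(got3, c("r3", "r1"))
})

test_that("population mode always returns a superset of surviving previous ids", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    rk <- ranked_fixture(paste0("r", sample(1000, n)),
                         sort(sample(50:500, n), decreasing = TRUE))
    prev <- sample(rk$read_id, sample(0:n, 1))
    got <- select_reads(rk, selection_policy("population"), cycle = 2,
                        previous_ids = prev)
    expect_true(all(prev %in% got))
  }
})

test_that("increment selection is a prefix of the next cycle's", {
  rk <- ranked_fixture(paste0("r", 1:95), seq(95, 1))
  pol <- selection_policy("increment", increment = 7)
  for (cyc in 1:12) {
    a <- select_reads(rk, pol, cycle = cyc)
    b <- select_reads(rk, pol, cycle = cyc + 1)
    expect_identical(a, b[seq_along(a)])
  }
})

test_that("manual mode signals exhaustion beyond the schedule", {
  rk <- ranked_fixture(paste0("r", 1:10), 10:1)
  pol <- selection_policy("manual", manual_counts = c(3, 6))
  expect_error(select_reads(rk, pol, cycle = 3),
               class = "manual_exhausted")
})

test_that("single fragmentation tiles without overlap and conserves bases", {
  r <- seq_record("x", random_seq(1800))
  fr <- fragment_single(r, 600)
  expect_equal(vapply(fr, function(f) nchar(f$sequence), 1L),
               c(600L, 600L, 600L))
  expect_equal(paste(vapply(fr, `[[`, "", "sequence"), collapse = ""),
               r$sequence)
  expect_equal(vapply(fr, `[[`, "", "id"),
               paste0("x_single_", 1:3))
  expect_equal(vapply(fr, function(f) f$offset, 1L), c(0L, 600L, 1200L))

  fr2 <- fragment_single(seq_record("y", random_seq(1500)), 600)
  expect_equal(vapply(fr2, function(f) nchar(f$sequence), 1L),
               c(600L, 600L, 300L))
  fr3 <- fragment_single(seq_record("z", random_seq(500)), 600)
  expect_length(fr3, 1)
  expect_equal(nchar(fr3[[1]]$sequence), 500L)
})

test_that("double fragmentation doubles apparent depth exactly", {
  r <- seq_record("x", random_seq(1220))
  fr <- fragment_double(r)  # defaults 610 / 490
  lens <- vapply(fr, function(f) nchar(f$sequence), 1L)
  expect_equal(sort(lens, decreasing = TRUE), c(610L, 610L, 490L, 490L,
                                                240L))
  expect_equal(sum(lens), 2L * 1220L)
  short <- fragment_double(seq_record("s", random_seq(400)))
  expect_equal(vapply(short, function(f) nchar(f$sequence), 1L),
               c(400L, 400L))
})

test_that("fragment base conservation holds for arbitrary reads and lengths", {
  set.seed(12)
  for (i in 1:25) {
    n <- sample(1:3000, 1)
    r <- seq_record("r", random_seq(n))
    L <- sample(1:800, 1)
    fr <- fragment_single(r, L)
    expect_equal(sum(vapply(fr, function(f) nchar(f$sequence), 1L)), n)
    expect_equal(paste(vapply(fr, `[[`, "", "sequence"), collapse = ""),
                 r$sequence)
    L2 <- L + sample(1:100, 1)
    fd <- fragment_double(r, L, L2)
    expect_equal(sum(vapply(fd, function(f) nchar(f$sequence), 1L)), 2L * n)
  }
})
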