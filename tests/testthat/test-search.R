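test_that("self-alignment yields a perfect forward hit", {
  set.seed(1)
  q <- random_seq(100)
  h <- align_local(q, c(s = q))
  expect_equal(nrow(h), 1)
  expect_equal(h$identity, 1)
  expect_equal(h$align_len, 100L)
  expect_equal(h$strand, "+")
  expect_equal(c(h$q_start, h$q_end, h$s_start, h$s_end), c(0, 100, 0, 100))
})

test_that("a reverse-complemented embedding is found on the minus strand", {
  set.seed(2)
  q <- random_seq(80)
  s <- paste0(random_seq(25), rc(q), random_seq(25))
  h <- align_local(q, c(s = s))
  expect_equal(h$strand[1], "-")
  expect_equal(h$identity[1], 1)
  expect_equal(c(h$s_start[1], h$s_end[1]), c(25, 105))
})

test_that("strand symmetry: hits of revcomp(q) mirror hits of q", {
  set.seed(3)
  for (i in 1:10) {
    q <- random_seq(sample(80:200, 1))
    s <- paste0(random_seq(30), mutate_subs(q, 3), random_seq(30))
    h1 <- align_local(q, c(s = s))
    h2 <- align_local(rc(q), c(s = s))
    expect_equal(nrow(h1), nrow(h2))
    expect_equal(h1$score, h2$score)
    expect_equal(h1$s_start, h2$s_start)
    expect_equal(h1$s_end, h2$s_end)
    expect_equal(h1$strand, chartr("+-", "-+", h2$strand))
  }
})

test_that("seed-and-extend scores equal the Smith-Waterman oracle", {
  set.seed(4)
  for (i in 1:40) {
    L <- sample(60:500, 1)
    a <- random_seq(L)
    b <- mutate_subs(a, rbinom(1, L, runif(1, 0, 0.08)))
    if (runif(1) < 0.4) b <- mutate_indels(b, sample(1:2, 1))
    h <- align_local(a, c(s = b))
    mine <- if (nrow(h)) h$score[1] else 0
    expect_equal(mine, sw_oracle_score(a, b), info = paste("trial", i))
  }
})

test_that("bitscore/e-value statistics follow the closed form", {
  sch <- scoring_scheme()
  be <- bitscore_evalue(50, 100, 1e6, sch)
  expect_equal(be$bitscore, (sch$lambda * 50 - log(sch$K)) / log(2))
  expect_equal(be$evalue, 100 * 1e6 * 2^(-be$bitscore))
  # doubling the database doubles E at fixed score
  expect_equal(bitscore_evalue(50, 100, 2e6, sch)$evalue, 2 * be$evalue)
  # monotone: larger raw score, larger bits, smaller E
  be2 <- bitscore_evalue(51, 100, 1e6, sch)
  expect_gt(be2$bitscore, be$bitscore)
  expect_lt(be2$evalue, be$evalue)
  # one extra bit halves E
  b0 <- bitscore_evalue(0, 10, 10, sch)
  expect_equal(10 * 10 * 2^(-b0$bitscore), b0$evalue)
})

test_that("six-frame translation follows the code table and truncation", {
  expect_equal(six_frame_translate("ATGAAA")[["+1"]], "MK")
  expect_equal(six_frame_translate("TTTCAT")[["-1"]], "MK")
  tr <- six_frame_translate(random_seq(7))
  expect_equal(nchar(tr[["+2"]]), 2)
  expect_equal(nchar(tr[["+1"]]), 2)
  expect_equal(nchar(tr[["+3"]]), 1)
})

test_that("search_store ranks the exact read first and respects cutoffs", {
  set.seed(5)
  reads <- lapply(1:30, function(i) seq_record(paste0("r", i),
                                               random_seq(150)))
  st <- read_store(reads)
  q <- reads[[7]]$sequence
  h <- search_store(list(seq_record("q", q)), st, evalue_cutoff = 1e-5)
  ranked <- attr(h, "ranked")
  expect_equal(ranked$read_id[1], "r7")
  # extreme stringency on unrelated reads returns nothing
  h2 <- search_store(list(seq_record("q", random_seq(150))), st,
                     evalue_cutoff = 1e-300)
  expect_equal(nrow(attr(h2, "ranked")), 0)
  expect_error(search_store(list(), st), "at least one")
})

test_that("planted motifs are recovered exactly, matching the oracle", {
  set.seed(6)
  motif <- random_seq(60)
  reads <- lapply(1:100, function(i) {
    s <- random_seq(300)
    if (i <= 20)
      s <- paste0(substr(s, 1, 120), motif, substr(s, 181, 300))
    seq_record(paste0("r", sprintf("%03d", i)), s)
  })
  st <- read_store(reads)
  h <- search_store(list(seq_record("m", motif)), st,
                    evalue_cutoff = 1e-10)
  got <- sort(attr(h, "ranked")$read_id)
  expect_equal(got, sprintf("r%03d", 1:20))
  # oracle confirmation on a sample: planted reads score 60, others below
  sc <- vapply(c(1, 10, 20, 21, 60), function(i)
    sw_oracle_score(motif, reads[[i]]$sequence), numeric(1))
  expect_true(all(sc[1:3] == 60))
  expect_true(all(sc[4:5] < 30))
})

test_that("tightening the e-value returns a subset of reads", {
  set.seed(7)
  src <- random_seq(4000)
  reads <- lapply(1:60, function(i) {
    s0 <- sample(3000, 1)
    seq_record(paste0("r", i),
               mutate_subs(substr(src, s0, s0 + sample(80:400, 1)),
                           sample(0:20, 1)))
  })
  st <- read_store(reads)
  q <- list(seq_record("q", substr(src, 1000, 2500)))
  loose <- attr(search_store(q, st, evalue_cutoff = 1e-10), "ranked")
  tight <- attr(search_store(q, st, evalue_cutoff = 1e-20), "ranked")
  expect_true(all(tight$read_id %in% loose$read_id))
})

test_that("protein queries find their coding region in either orientation", {
  set.seed(8)
  read <- random_seq(300)
  prot <- gsub("*", "S", six_frame_translate(read)[["+2"]], fixed = TRUE)
  q <- seq_record("p", substr(prot, 10, 60))
  h <- align_local(q, c(r = read), scheme = scoring_scheme("protein"))
  expect_gt(nrow(h), 0)
  expect_equal(h$frame[1], 2L)
  expect_equal(h$strand[1], "+")
  # nucleotide coordinates map back into the read
  expect_true(h$s_start[1] >= 0 && h$s_end[1] <= 300)
  expect_equal((h$s_end[1] - h$s_start[1]) %% 3, 0)
  h2 <- align_local(q, c(r = rc(read)), scheme = scoring_scheme("protein"))
  expect_equal(h2$frame[1], -2L)
  expect_equal(h2$strand[1], "-")
})

test_that("empty query errors; short subjects yield no hits", {
  expect_error(align_local("", c(s = "ACGT")), "empty")
  h <- align_local(random_seq(50), c(s = "ACGTACG"))
  expect_equal(nrow(h), 0)
})
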