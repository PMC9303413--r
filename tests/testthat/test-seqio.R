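test_that("FASTA parsing follows header-token, folding and case rules", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT"), p)
  r <- read_fasta(p)
  expect_length(r, 1)
  expect_equal(r[[1]]$id, "a")
  expect_equal(r[[1]]$sequence, "ACGT")

  writeLines(c(">a", "AC", "GT", ">b", "TTTT"), p)
  r <- read_fasta(p)
  expect_length(r, 2)
  expect_equal(r[[1]]$sequence, "ACGT")
  expect_equal(r[[2]]$sequence, "TTTT")

  writeLines(c(">a x y", "acgt"), p)
  r <- read_fasta(p)
  expect_equal(r[[1]]$id, "a")
  expect_equal(r[[1]]$sequence, "ACGT")
})

test_that("FASTA parse errors name the offending line", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ACGT", ">a"), p)
  expect_error(read_fasta(p), "line 1")
  writeLines(c(">a", "ACGT", ">b", ">c", "AAAA"), p)
  expect_error(read_fasta(p), "line 3")
})

test_that("U and ambiguity codes are normalized on nucleotide ingest", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGUACGU"), p)
  expect_equal(read_fasta(p)[[1]]$sequence, "ACGTACGT")
  writeLines(c(">a", "ACGTRYACGTACGTACGTAC"), p)
  expect_warning(r <- read_fasta(p, alphabet = "nucleotide"), "ambiguity")
  expect_equal(r[[1]]$sequence, "ACGTNNACGTACGTACGTAC")
})

test_that("FASTQ qualities decode with configurable offset and mates link", {
  p <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r", "ACGT", "+", "IIII"), p)
  r <- read_fastq(p)
  expect_equal(r[[1]]$qualities, rep(40L, 4))
  r64 <- read_fastq(p, offset = 64L)
  expect_equal(r64[[1]]$qualities, rep(9L, 4))

  p2 <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r/1", "ACGT", "+", "IIII"), p)
  writeLines(c("@r/2", "TTTT", "+", "IIII"), p2)
  pair <- read_fastq(p, p2)
  expect_equal(pair[[1]]$mate_of, "r/2")
  expect_equal(pair[[2]]$mate_of, "r/1")
})

test_that("FASTQ length mismatch is a parse error", {
  p <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r", "ACGT", "+", "III"), p)
  expect_error(read_fastq(p), "length")
})

test_that("write_fasta wraps lines and round-trips losslessly", {
  p <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(c(c1 = "ACGT"), p)
  expect_equal(readLines(p), c(">c1", "ACGT"))

  long <- paste(rep("ACGTA", 26), collapse = "")  # 130 nt
  write_fasta(c(x = long), p)
  expect_equal(length(readLines(p)), 1 + 3)

  set.seed(101)
  for (rep_i in 1:10) {
    n <- sample(1:8, 1)
    recs <- lapply(seq_len(n), function(i)
      seq_record(paste0("s", i), random_seq(sample(1:300, 1))))
    write_fasta(recs, p)
    back <- read_fasta(p)
    expect_equal(unname(vapply(back, `[[`, "", "id")),
                 vapply(recs, `[[`, "", "id"))
    expect_equal(unname(vapply(back, `[[`, "", "sequence")),
                 vapply(recs, `[[`, "", "sequence"))
  }
})

test_that("read store indexes by id, keeps order, rejects duplicates", {
  recs <- list(seq_record("a", "ACGT"), seq_record("b", "GGCC"))
  st <- read_store(recs)
  expect_equal(store_ids(st), c("a", "b"))
  expect_equal(store_get(st, "b")[[1]]$sequence, "GGCC")
  expect_equal(store_nbases(st), 8)
  expect_error(store_add(st, list(seq_record("a", "TT"))), "duplicate")
  expect_error(store_get(st, "zz"), "not found")
})

test_that("store round-trips through disk", {
  d <- withr::local_tempdir()
  st <- read_store(list(seq_record("a", "ACGTACGT"),
                        seq_record("b", "GGCCGGCC")))
  store_save(st, d)
  st2 <- store_load(d)
  expect_equal(store_ids(st2), c("a", "b"))
  expect_equal(store_get(st2, "a")[[1]]$sequence, "ACGTACGT")
})
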