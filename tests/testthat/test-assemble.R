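test_that("a constructed dovetail overlap is found with exact geometry", {
  set.seed(21)
  S <- random_seq(50)
  X <- paste0(random_seq(100), S)
  Y <- paste0(S, random_seq(100))
  ov <- find_overlaps(c(x = X, y = Y), assembler_params())
  expect_equal(nrow(ov), 1)
  expect_equal(ov$length, 50L)
  expect_equal(ov$identity, 1)
  expect_equal(ov$orientation, "same")
  expect_equal(c(ov$a_start, ov$a_end), c(100L, 150L))
  expect_equal(c(ov$b_start, ov$b_end), c(0L, 50L))

  # one mismatch inside the shared block: identity 49/50
  S2 <- mutate_subs(S, 1)
  ov2 <- find_overlaps(c(x = X, y = paste0(S2, random_seq(100))),
                       assembler_params())
  expect_equal(ov2$identity, 49 / 50)
})

test_that("overlap detection agrees with a brute-force all-pairs oracle", {
  set.seed(22)
  for (trial in 1:5) {
    src <- random_seq(1500)
    reads <- tiling_reads(src, read_len = 200, step = sample(100:140, 1))
    got <- find_overlaps(reads, assembler_params())
    want <- oracle_overlaps(as.list(reads))
    key <- function(d) sort(paste(d$i, d$j, d$orientation, d$length))
    got$i <- match(got$read_a, names(reads))
    got$j <- match(got$read_b, names(reads))
    expect_equal(key(got), key(want), info = paste("trial", trial))
  }
})

test_that("error-free tilings reassemble to the exact source", {
  set.seed(23)
  src <- random_seq(300)
  reads <- setNames(vapply(c(1, 51, 101, 151, 201),
                           function(s) substr(src, s, s + 99), ""),
                    paste0("r", 1:5))
  ctg <- greedy_assemble(reads, assembler_params())
  expect_length(ctg, 1)
  expect_true(ctg[[1]]$sequence == src || ctg[[1]]$sequence == rc(src))
  expect_equal(ctg[[1]]$n_reads, 5L)
})

test_that("disjoint read clusters assemble into separate contigs", {
  set.seed(24)
  a <- random_seq(800); b <- random_seq(800)
  reads <- c(tiling_reads(a, 300, 150), setNames(tiling_reads(b, 300, 150),
                                                 paste0("u", 1:5)))
  ctg <- greedy_assemble(reads, assembler_params())
  expect_length(ctg, 2)
})

test_that("overlaps below min_overlap leave only droppable singletons", {
  set.seed(25)
  reads <- c(r1 = random_seq(200), r2 = random_seq(200))
  expect_length(greedy_assemble(reads, assembler_params()), 0)
  kept <- greedy_assemble(reads, assembler_params(keep_singletons = TRUE))
  expect_length(kept, 2)
  expect_equal(kept[[1]]$n_reads, 1L)
})

test_that("consensus column votes use weights with fixed-order ties", {
  expect_equal(consensus_base(c("A", "A", "G")), "A")
  expect_equal(consensus_base(c("A", "G")), "A")        # tie: A < G
  expect_equal(consensus_base(c("A", "G"), c(10, 40)), "G")
  expect_equal(consensus_base(c("T", "-", "-")), "-")
})

test_that("contig depth equals the number of layout reads spanning each column", {
  set.seed(26)
  src <- random_seq(2000)
  reads <- tiling_reads(src, read_len = 400, step = 150)
  ctg <- greedy_assemble(reads, assembler_params())
  expect_length(ctg, 1)
  ct <- ctg[[1]]
  lay <- ct$layout
  for (p in sort(sample(nchar(ct$sequence), 25))) {
    expect_equal(ct$depth[p],
                 sum(lay$contig_start < p & lay$contig_end >= p),
                 info = paste("column", p))
  }
  # every layout read realigns at its placement
  for (i in sample(nrow(lay), 5)) {
    sub <- substr(ct$sequence, lay$contig_start[i] + 1, lay$contig_end[i])
    r <- reads[[lay$read_id[i]]]
    if (lay$orientation[i] == "-") r <- rc(r)
    expect_equal(sub, r)
  }
})

test_that("nine-allele simulations produce chimeric or consensus contigs", {
  # a single seed here; the multi-seed stochastic claim lives in the
  # acceptance suite
  set.seed(27)
  sim <- simulate_locus_reads(locus_model(founder_len = 3500,
                                          core_len = 900),
                              read_profile("length_file"), coverage = 5)
  ctg <- greedy_assemble(sim$reads, assembler_params())
  expect_true(length(ctg) != length(sim$alleles) ||
                any(vapply(ctg, function(ct)
                  length(unique(source_allele(ct$layout$read_id))) > 1,
                  logical(1))))
})

test_that("the external assembler contract errors helpfully and parses contig FASTA", {
  expect_error(
    external_assembler(c(r1 = "ACGT"),
                       list(name = "definitely-not-a-real-assembler",
                            command = "x {reads} {out}")),
    "built-in")
  fx <- system.file("extdata", "external_contigs.fasta",
                    package = "seedasm")
  ctg <- parse_contig_fasta(fx)
  expect_length(ctg, 2)
  expect_equal(ctg[[1]]$id, "Contig1")
  expect_equal(nchar(ctg[[1]]$sequence), 76)
  expect_equal(nrow(ctg[[1]]$layout), 0)
})
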