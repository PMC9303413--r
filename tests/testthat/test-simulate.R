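test_that("the founder generator honours length, frequencies and the seed", {
  set.seed(41)
  f <- make_founder(locus_model())
  expect_equal(nchar(f), 7000)
  set.seed(41)
  expect_identical(make_founder(locus_model()), f)
  allA <- make_founder(locus_model(founder_len = 50, core_len = 10),
                       base_freqs = c(1, 0, 0, 0))
  expect_equal(allA, strrep("A", 50))
})

test_that("alleles mutate at the core and flank rates", {
  set.seed(42)
  f <- make_founder(locus_model())
  # zero rates: identical alleles
  same <- make_alleles(f, locus_model(p_mut_core = 0, p_mut_flank = 0))
  expect_true(all(same == f))

  # default rates: SNP count ~ Binomial(1800, .005) + Binomial(5200, .02),
  # mean 113, checked within 3 sigma over 100 alleles
  al <- make_alleles(f, locus_model(n_alleles = 100))
  snps <- attr(al, "snps")
  mean_expect <- 1800 * 0.005 + 5200 * 0.02
  sd_expect <- sqrt(1800 * 0.005 * 0.995 + 5200 * 0.02 * 0.98)
  per_allele <- as.numeric(table(factor(snps$allele,
                                        levels = paste0("allele", 1:100))))
  expect_lt(abs(mean(per_allele) - mean_expect),
            3 * sd_expect / sqrt(100))

  # SNP density lower in the core than in the flanks
  core <- seq(2601, length.out = 1800)
  dens_core <- sum(snps$pos %in% core) / 1800
  dens_flank <- sum(!snps$pos %in% core) / 5200
  expect_lt(dens_core, dens_flank)
})

test_that("read drawing hits the coverage target and encodes truth", {
  set.seed(43)
  g <- c(ref = random_seq(10000))
  reads <- draw_reads(g, read_profile("length_file", lengths = 500L),
                      coverage = 5)
  expect_equal(length(reads), 100)  # 5 x 10000 / 500
  truth <- attr(reads, "truth")
  expect_equal(nrow(truth), 100)
  # ids encode source / position / strand; sequences match the source
  for (i in sample(100, 10)) {
    tr <- truth[i, ]
    s <- substr(g[["ref"]], tr$start, tr$start + tr$src_len - 1)
    if (tr$strand == "-") s <- rc(s)
    expect_equal(reads[[i]]$sequence, s)
  }
})

test_that("paired reads come as opposite-strand mates with /1 /2 ids", {
  set.seed(44)
  reads <- draw_reads(c(ref = random_seq(8000)),
                      read_profile("paired_short"), coverage = 2)
  truth <- attr(reads, "truth")
  expect_true(all(grepl("/[12]$", truth$read_id)))
  p1 <- truth[seq(1, nrow(truth), by = 2), ]
  p2 <- truth[seq(2, nrow(truth), by = 2), ]
  expect_true(all(p1$strand != p2$strand))
  expect_true(all(p1$src_len == 150))
  expect_equal(reads[[1]]$mate_of, reads[[2]]$id)
  expect_equal(reads[[2]]$mate_of, reads[[1]]$id)
})

test_that("long reads span 7-14 kb", {
  set.seed(45)
  reads <- draw_reads(c(ref = random_seq(50000)), read_profile("long"),
                      coverage = 1.5)
  lens <- vapply(reads, function(r) nchar(r$sequence), 1L)
  expect_true(all(lens >= 7000 & lens <= 14000))
})

test_that("the error channels behave at their extremes", {
  set.seed(46)
  r <- seq_record("r", random_seq(2000))
  same <- apply_errors(r, error_model())
  expect_equal(same$sequence, r$sequence)
  expect_equal(nrow(attr(same, "events")), 0)

  forced <- apply_errors(r, error_model(p_sub = 1))
  a <- strsplit(r$sequence, "")[[1]]
  b <- strsplit(forced$sequence, "")[[1]]
  expect_equal(sum(a == b), 0)
})

test_that("realized channel rates are binomially consistent", {
  set.seed(47)
  n <- 200000
  r <- seq_record("r", random_seq(n))
  em <- error_model(p_sub = 0.01, p_del = 0.004, p_ins = 0.004)
  out <- apply_errors(r, em)
  ev <- attr(out, "events")
  for (ch in c("sub", "del", "ins")) {
    p <- switch(ch, sub = 0.01, del = 0.004, ins = 0.004)
    k <- sum(ev$type == ch)
    expect_lt(abs(k - n * p), 3 * sqrt(n * p * (1 - p)),
              label = paste(ch, "count", k))
  }
})

test_that("simulation is deterministic under a fixed seed", {
  set.seed(48)
  a <- simulate_locus_reads(locus_model(founder_len = 2000,
                                        core_len = 600),
                            read_profile("length_file"), coverage = 2,
                            em = error_model_short())
  set.seed(48)
  b <- simulate_locus_reads(locus_model(founder_len = 2000,
                                        core_len = 600),
                            read_profile("length_file"), coverage = 2,
                            em = error_model_short())
  expect_identical(a$alleles, b$alleles)
  expect_identical(vapply(a$reads, `[[`, "", "sequence"),
                   vapply(b$reads, `[[`, "", "sequence"))
})
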