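test_that("contig accuracy is exact for reference substrings", {
  set.seed(51)
  ref <- c(chr = random_seq(3000))
  acc <- contig_accuracy(c(c1 = substr(ref, 500, 1200)), ref)
  expect_equal(acc$identity, 1)
  expect_equal(acc$ref_id, "chr")
  expect_false(acc$no_hit)
  # no-hit contigs flagged with identity 0
  acc0 <- contig_accuracy(c(c2 = random_seq(300)), ref)
  expect_equal(acc0$identity, 0)
  expect_true(acc0$no_hit)
})

test_that("terminal and middle mismatches split as defined", {
  set.seed(52)
  ref <- c(chr = random_seq(1000))
  ctg <- substr(ref, 301, 700)  # 400 nt
  ch <- strsplit(ctg, "")[[1]]
  flip <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  for (p in c(20, 80)) ch[p] <- flip(ch[p])   # first 100
  ch[200] <- flip(ch[200])                    # middle
  acc <- contig_accuracy(c(c1 = paste(ch, collapse = "")), ref)
  expect_equal(acc$mismatches_terminal, 2L)
  expect_equal(acc$mismatches_middle, 1L)
  expect_equal(acc$len_terminal, 200L)
  expect_equal(acc$len_middle, 200L)
  expect_equal(acc$mismatches_terminal / acc$len_terminal, 0.01)
  expect_equal(acc$mismatches_middle / acc$len_middle, 0.005)
})

test_that("trajectory classification follows the documented rules", {
  expect_equal(classify_trajectory(c(10, 20, 30)), "monotone")
  expect_equal(classify_trajectory(c(10, 30, 10, 30)), "alternating")
  expect_equal(classify_trajectory(c(10, 10, 10)), "flat")
  expect_equal(classify_trajectory(c(10, 20, 20, 30)), "stepwise")
  expect_equal(classify_trajectory(c(10, 40, 15)), "peaked")
  expect_equal(classify_trajectory(c(40, 30, 20)), "irregular")
})

test_that("trajectory_stats reproduces the report quantities", {
  rep <- data.frame(cycle = 1:3, n_reads_selected = c(10, 20, 30),
                    n_contigs_all = c(2, 3, 4),
                    n_contigs_matching = c(1, 1, 2),
                    longest_all = c(500, 800, 900),
                    longest_matching = c(500, 700, 900),
                    mean_len_all = c(400, 500, 450),
                    mean_len_matching = c(500, 700, 800),
                    stop_reason = NA_character_)
  tab <- trajectory_stats(rep)
  expect_equal(ncol(tab), 8)
  expect_equal(attr(tab, "shape"), "monotone")
})

test_that("lengthening ratios bin in 0.4 steps with closed-open bounds", {
  expect_equal(unname(lengthening_bins(c(1.39))), c(1, 0, 0, 0, 0, 0))
  expect_equal(unname(lengthening_bins(c(1.40))), c(0, 1, 0, 0, 0, 0))
  expect_equal(unname(lengthening_bins(c(1.0, 2.0, 3.5))),
               c(1, 0, 1, 0, 0, 1))
  expect_warning(b <- lengthening_bins(c(0.9)), "first bin")
  expect_equal(unname(b), c(1, 0, 0, 0, 0, 0))
})

test_that("locus calling merges book-ended hits and splits at the gap", {
  # overlapping hits: one locus, one distinct hit
  l1 <- call_loci(data.frame(ref_id = "r", start = c(100, 450),
                             end = c(500, 900)))
  expect_equal(nrow(l1), 1)
  expect_equal(c(l1$start, l1$end, l1$n_hits), c(100, 900, 1))

  # separated hits within the gap: one locus, two distinct hits
  l2 <- call_loci(data.frame(ref_id = "r", start = c(100, 600, 15000),
                             end = c(500, 900, 15400)))
  expect_equal(nrow(l2), 2)
  expect_equal(l2$n_hits, c(2, 1))
  expect_equal(l2$start, c(100, 15000))

  expect_equal(nrow(call_loci(NULL)), 0)
})

test_that("locus calls are invariant to hit order", {
  set.seed(53)
  hits <- data.frame(ref_id = sample(c("a", "b"), 40, replace = TRUE),
                     start = sample(1e6, 40))
  hits$end <- hits$start + sample(500:5000, 40, replace = TRUE)
  a <- call_loci(hits)
  b <- call_loci(hits[sample(nrow(hits)), ])
  expect_equal(a, b)
})

test_that("scalar statistics follow their closed forms", {
  expect_equal(contig_loci_ratio(10, 10), 1)
  expect_equal(round(contig_loci_ratio(25.5, 34.9), 2), 0.73)
  expect_equal(contig_loci_ratio(0, 5), 0)
  expect_error(contig_loci_ratio(3, 0), "positive")

  expect_equal(round(primer_match_prob(0.990, 20, 20), 3), 0.669)
  expect_equal(round(primer_match_prob(0.995, 20, 20), 3), 0.818)
  expect_equal(primer_match_prob(1, 25, 30), 1)

  expect_equal(round(coverage_fold(87.4e9, 2.4e9), 1), 36.4)
  expect_equal(round(coverage_fold(178.5e9, 17e9), 1), 10.5)
  expect_equal(coverage_fold(5, 5), 1)

  expect_equal(region_span_sum(list(c(1, 10))), 10)
  expect_equal(region_span_sum(list()), 0)
  expect_equal(region_span_sum(list(c(559066659, 596637530),
                                    c(627849254, 696738616),
                                    c(454010413, 496939616))),
               149389439)
})

test_that("SNP anchor scanning reports contig-specific pairs only", {
  set.seed(54)
  base <- random_seq(1200)
  flip <- function(s, p) {
    substr(s, p, p) <- setdiff(c("A", "C", "G", "T"),
                               substr(s, p, p))[1]
    s
  }
  a <- base
  b <- flip(flip(base, 200), 900)
  # identical contigs: nothing is contig-specific
  none <- snp_anchor_scan(c(x = base, y = base), min_depth = 1,
                          min_product = 100, max_product = 2000)
  expect_equal(nrow(none), 0)

  res <- snp_anchor_scan(c(x = a, y = b), min_depth = 1,
                         min_product = 600, max_product = 1100)
  for (ctg in c("x", "y")) {
    r <- res[res$contig_id == ctg, ]
    expect_equal(nrow(r), 1)
    expect_equal(c(r$position, r$paired_with), c(200, 900))
  }
  # outside the product window: no pairs
  res2 <- snp_anchor_scan(c(x = a, y = b), min_depth = 1,
                          min_product = 750, max_product = 1100)
  expect_equal(nrow(res2), 0)

  # a position shared with any nonself contig is not specific
  c3 <- flip(base, 200)  # agrees with b at 200? no - differs from both at none
  res3 <- snp_anchor_scan(c(x = a, y = b, z = c3), min_depth = 2,
                          min_product = 600, max_product = 1100)
  # contig b's base at 200 equals c3's variant or base's? b and c3 both
  # flipped 200 the same way, so b at 200 now agrees with z: not specific
  expect_equal(nrow(res3[res3$contig_id == "y", ]), 0)
})

test_that("anchor scanning is invariant to contig relabeling", {
  set.seed(55)
  base <- random_seq(900)
  v <- vapply(1:3, function(i) mutate_subs(base, 4), character(1))
  names(v) <- c("p", "q", "r")
  a <- snp_anchor_scan(v, min_depth = 1, min_product = 50,
                       max_product = 800)
  v2 <- v[c(3, 1, 2)]
  b <- snp_anchor_scan(v2, min_depth = 1, min_product = 50,
                       max_product = 800)
  key <- function(d) sort(paste(d$contig_id, d$position, d$paired_with))
  expect_equal(key(a), key(b))
})
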