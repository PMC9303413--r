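# Measurement procedures: contig accuracy vs a reference, trajectory
# statistics, lengthening bins, locus calling, SNP anchor scanning, and the
# small closed-form statistics used alongside them.

#' Contig accuracy against a reference
#'
#' Best local alignment per contig; identity = matches / alignment length.
#' Mismatching columns are split between the terminal segments (the first
#' and last `terminal` contig bases of the alignment) and the middle.
#' Contigs with no hit are reported with identity 0 and `no_hit = TRUE`.
#'
#' @param contigs List of `contig` / [seq_record()] or named character.
#' @param reference Named character vector (or list of records) of
#'   reference sequences.
#' @param scheme Nucleotide [scoring_scheme()].
#' @param terminal Terminal segment width (default 100).
#' @param band_pad Band slack for the alignments.
#' @return Data frame with one row per contig: `contig_id`, `ref_id`,
#'   `identity`, `align_len`, `mismatches_terminal`, `mismatches_middle`,
#'   `len_terminal`, `len_middle`, `no_hit`.
#' @export
contig_accuracy <- function(contigs, reference, scheme = scoring_scheme(),
                            terminal = 100L, band_pad = 200L) {
  rv <- as_named_seqs(reference)
  if (!length(rv)) stop("empty reference")
  cv <- as_named_seqs(contigs)
  out <- lapply(seq_along(cv), function(i) {
    h <- align_local(setNames(cv[i], names(cv)[i]), rv, scheme = scheme,
                     band_pad = band_pad, want_path = TRUE)
    if (nrow(h) == 0L)
      return(data.frame(contig_id = names(cv)[i], ref_id = NA_character_,
                        identity = 0, align_len = 0L,
                        mismatches_terminal = 0L, mismatches_middle = 0L,
                        len_terminal = 0L, len_middle = 0L, no_hit = TRUE,
                        stringsAsFactors = FALSE))
    h <- h[1L, ]
    opv <- strsplit(h$path, "", fixed = TRUE)[[1]]
    qpos <- h$q_start + cumsum(opv != "I")  # contig base per column
    ch_q <- strsplit(cv[[i]], "", fixed = TRUE)[[1]]
    # error columns: mismatched M plus any gap column
    sidx <- h$s_start + cumsum(opv != "D")
    ch_s <- strsplit(rv[[h$subject_id]], "", fixed = TRUE)[[1]]
    if (h$strand == "-") {
      # path is in subject-forward frame with the query reversed; reflect
      # query positions back to the forward contig
      qpos <- nchar(cv[[i]]) - qpos + 1L
      ch_qq <- strsplit(as.character(revcomp(cv[[i]])), "",
                        fixed = TRUE)[[1]]
      qb <- ch_qq[h$q_start + cumsum(opv != "I")]
    } else qb <- ch_q[qpos]
    err <- opv != "M" | qb != ch_s[sidx]
    qa <- h$q_end - h$q_start                 # aligned contig bases
    qlo <- min(qpos); qhi <- max(qpos)
    is_term <- qpos <= qlo + terminal - 1L | qpos >= qhi - terminal + 1L
    len_term <- length(unique(qpos[is_term]))
    len_mid <- length(unique(qpos[!is_term]))
    data.frame(contig_id = names(cv)[i], ref_id = h$subject_id,
               identity = h$identity, align_len = h$align_len,
               mismatches_terminal = sum(err & is_term),
               mismatches_middle = sum(err & !is_term),
               len_terminal = len_term, len_middle = len_mid,
               no_hit = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-cycle trajectory statistics and shape classification
#'
#' @param reports A cycle-report data frame from [run_pipeline()].
#' @return The 8-column trajectory table (cycle, longest/mean/count for
#'   matching and all contigs, and `n_reads_selected`) with the shape label
#'   of the longest-matching trajectory as attribute `"shape"` (see
#'   [classify_trajectory()]).
#' @export
trajectory_stats <- function(reports) {
  stopifnot(nrow(reports) >= 1L)
  tab <- reports[, c("cycle", "longest_matching", "mean_len_matching",
                     "n_contigs_matching", "longest_all", "mean_len_all",
                     "n_contigs_all", "n_reads_selected")]
  attr(tab, "shape") <- classify_trajectory(reports$longest_matching)
  tab
}

#' Classify a contig-length trajectory
#'
#' Simple documented heuristics on the per-cycle longest lengths:
#' `monotone` (every step up), `stepwise` (never down, growth resumes after
#' a plateau), `alternating` (the differences change sign at least twice),
#' `peaked` (one interior maximum, up then down), `flat` (no change),
#' otherwise `irregular`.
#'
#' @param lengths Numeric vector of per-cycle lengths.
#' @return One of the labels above.
#' @export
classify_trajectory <- function(lengths) {
  if (length(lengths) < 2L) return("flat")
  d <- diff(lengths)
  if (all(d == 0)) return("flat")
  if (all(d >= 0)) {
    z <- which(d == 0)
    if (length(z) && any(z < max(which(d > 0)))) return("stepwise")
    return("monotone")
  }
  s <- sign(d[d != 0])
  changes <- sum(diff(s) != 0)
  if (changes >= 2L) return("alternating")
  if (changes == 1L && s[1L] > 0) return("peaked")
  "irregular"
}

#' Bin contig lengthening ratios
#'
#' Ratios of maximum-over-cycles to cycle-1 longest contig length, binned in
#' increments of 0.4: [1.00,1.40), [1.40,1.80), [1.80,2.20), [2.20,2.60),
#' [2.60,3.00), [3.00,Inf). By construction (the maximum includes cycle 1)
#' ratios below 1 cannot arise; if supplied they are counted in the first
#' bin with a warning.
#'
#' @param ratios Numeric vector of lengthening ratios.
#' @return Named integer vector of six bin counts.
#' @export
lengthening_bins <- function(ratios) {
  if (any(ratios < 1)) {
    warning("ratios below 1 counted in the first bin")
    ratios[ratios < 1] <- 1
  }
  br <- c(1, 1.4, 1.8, 2.2, 2.6, 3, Inf)
  counts <- table(cut(ratios, br, right = FALSE, include.lowest = TRUE))
  out <- as.integer(counts)
  names(out) <- c("1.00-1.39", "1.40-1.79", "1.80-2.19", "2.20-2.59",
                  "2.60-2.99", "3.00+")
  out
}

#' Call loci from alignment hit intervals
#'
#' Per reference: hit intervals are sorted by start; a new distinct hit is
#' counted where a start exceeds the previous running end; a new locus opens
#' where the gap from the previous locus end exceeds `gap` bases.
#'
#' @param hits Data frame with columns `ref_id`, `start`, `end` (1-based
#'   inclusive).
#' @param gap Minimum between-locus gap (default 10000).
#' @return Data frame of loci: `ref_id`, `start`, `end`, `n_hits`. The
#'   result does not depend on the input row order.
#' @export
call_loci <- function(hits, gap = 10000L) {
  empty <- data.frame(ref_id = character(0), start = integer(0),
                      end = integer(0), n_hits = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  stopifnot(all(hits$start <= hits$end))
  out <- lapply(split(hits, hits$ref_id), function(h) {
    h <- h[order(h$start, h$end), ]
    loci <- list()
    cur_s <- h$start[1L]; cur_e <- h$end[1L]; nh <- 1L; prev_e <- h$end[1L]
    for (i in seq_len(nrow(h))[-1L]) {
      if (h$start[i] > cur_e + gap) {
        loci[[length(loci) + 1L]] <- c(cur_s, cur_e, nh)
        cur_s <- h$start[i]; cur_e <- h$end[i]; nh <- 1L
      } else {
        if (h$start[i] > cur_e) nh <- nh + 1L
        cur_e <- max(cur_e, h$end[i])
      }
    }
    loci[[length(loci) + 1L]] <- c(cur_s, cur_e, nh)
    m <- do.call(rbind, loci)
    data.frame(ref_id = h$ref_id[1L], start = m[, 1L], end = m[, 2L],
               n_hits = m[, 3L], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Contig-to-locus ratio
#' @param n_contigs Number of assembled contigs.
#' @param n_loci Number of called loci (> 0).
#' @return `n_contigs / n_loci`.
#' @export
contig_loci_ratio <- function(n_contigs, n_loci) {
  if (n_loci <= 0) stop("n_loci must be positive")
  n_contigs / n_loci
}

#' Probability that two primers match an assembly exactly
#'
#' With per-base assembly accuracy `x`, the chance that two primers of
#' lengths `m` and `n` both match exactly is `x^(m+n)`.
#'
#' @param x Per-base accuracy in `[0,1]`.
#' @param m,n Primer lengths (>= 1).
#' @return `x^(m+n)`.
#' @export
primer_match_prob <- function(x, m, n) {
  stopifnot(all(x >= 0), all(x <= 1), all(m >= 1), all(n >= 1))
  x^(m + n)
}

#' Fold coverage from total bases and genome size
#' @param total_bases Total sequenced bases.
#' @param genome_size Genome size in bases (> 0).
#' @return `total_bases / genome_size`.
#' @export
coverage_fold <- function(total_bases, genome_size) {
  stopifnot(genome_size > 0)
  total_bases / genome_size
}

#' Sum of 1-based inclusive interval lengths
#' @param ranges Two-column matrix / data frame (start, end) or a list of
#'   length-2 vectors.
#' @return Integer-valued total `sum(end - start + 1)`.
#' @export
region_span_sum <- function(ranges) {
  if (is.list(ranges) && !is.data.frame(ranges))
    ranges <- do.call(rbind, ranges)
  if (length(ranges) == 0L) return(0)
  ranges <- as.matrix(ranges)
  stopifnot(ncol(ranges) == 2L, all(ranges[, 1L] <= ranges[, 2L]))
  sum(ranges[, 2L] - ranges[, 1L] + 1)
}

#' Scan contigs for contig-specific SNP primer anchors
#'
#' All-vs-all local alignment at the given e-value (self-hits excluded)
#' yields, for every contig position, the nonself coverage depth and the
#' aligned nonself bases. Within the interval between the first and last
#' positions where depth >= `min_depth`, a position is an anchor candidate
#' when the contig base differs from every aligned nonself base (or, with
#' `strict = TRUE`, when no nonself contig aligns there at all). Candidate
#' pairs separated by at least `min_product` but at most `max_product`
#' bases are reported as anchor sites.
#'
#' @param contigs >= 2 contigs (list or named character).
#' @param evalue E-value cutoff for the mutual alignments (default 1e-08).
#' @param min_depth Minimum mutual-alignment depth bounding the scanned
#'   interval (required; no default is implied by the procedure).
#' @param min_product,max_product Allowed anchor-pair separation (bases).
#' @param strict Use the no-nonself-coverage reading instead of the
#'   all-disagree reading.
#' @param scheme Nucleotide [scoring_scheme()].
#' @return Data frame of anchor pairs: `contig_id`, `position`,
#'   `paired_with` (1-based positions). Relabeling contigs permutes but
#'   does not change the set.
#' @export
snp_anchor_scan <- function(contigs, evalue = 1e-08, min_depth,
                            min_product, max_product, strict = FALSE,
                            scheme = scoring_scheme()) {
  cv <- as_named_seqs(contigs)
  if (length(cv) < 2L) stop("need at least two contigs")
  stopifnot(min_product <= max_product, min_depth >= 1L)
  out <- list()
  for (i in seq_along(cv)) {
    L <- nchar(cv[[i]])
    depth <- integer(L)
    agree <- logical(L)   # some nonself base equals the contig base
    ch <- strsplit(cv[[i]], "", fixed = TRUE)[[1]]
    for (j in seq_along(cv)) {
      if (i == j) next
      h <- align_local(setNames(cv[i], names(cv)[i]),
                       setNames(cv[j], names(cv)[j]), scheme = scheme,
                       want_path = TRUE)
      h <- h[h$evalue <= evalue, , drop = FALSE]
      if (!nrow(h)) next
      for (t in seq_len(nrow(h))) {
        opv <- strsplit(h$path[t], "", fixed = TRUE)[[1]]
        qpos <- h$q_start[t] + cumsum(opv != "I")
        spos <- h$s_start[t] + cumsum(opv != "D")
        other <- strsplit(cv[[j]], "", fixed = TRUE)[[1]]
        if (h$strand[t] == "-") {
          qpos <- L - qpos + 1L
          qb_rc <- strsplit(as.character(revcomp(cv[[i]])), "",
                            fixed = TRUE)[[1]]
        }
        isM <- opv == "M"
        qp <- qpos[isM]; sp <- spos[isM]
        depth[qp] <- depth[qp] + 1L
        same <- if (h$strand[t] == "-")
          qb_rc[h$q_start[t] + cumsum(opv != "I")][isM] == other[sp]
        else ch[qp] == other[sp]
        agree[qp[same]] <- TRUE
      }
    }
    ok <- which(depth >= min_depth)
    if (!length(ok)) next
    lo <- min(ok); hi <- max(ok)
    cand <- if (strict) which(depth == 0L) else
      which(depth >= 1L & !agree)
    cand <- cand[cand >= lo & cand <= hi]
    if (length(cand) >= 2L) {
      prs <- which(outer(cand, cand, function(a, b) {
        d <- b - a
        d >= min_product & d <= max_product
      }), arr.ind = TRUE)
      prs <- prs[prs[, 1L] < prs[, 2L], , drop = FALSE]
      if (nrow(prs))
        out[[length(out) + 1L]] <- data.frame(
          contig_id = names(cv)[i], position = cand[prs[, 1L]],
          paired_with = cand[prs[, 2L]], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(contig_id = character(0), position = integer(0),
                      paired_with = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$contig_id, res$position, res$paired_with), ]
  rownames(res) <- NULL
  res
}
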