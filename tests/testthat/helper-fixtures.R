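# Shared fixture generators and independent oracles.

BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

# substitutions at given positions (or a count at random positions)
mutate_subs <- function(seq, n_sub) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (n_sub == 0) return(seq)
  idx <- sample(length(ch), n_sub)
  ch[idx] <- vapply(ch[idx], function(b) sample(setdiff(BASES, b), 1),
                    character(1))
  paste(ch, collapse = "")
}

# random small indels
mutate_indels <- function(seq, n_events, max_len = 3) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in seq_len(n_events)) {
    pos <- sample(length(ch), 1)
    len <- sample(max_len, 1)
    if (runif(1) < 0.5) {
      ch <- append(ch, sample(BASES, len, replace = TRUE), after = pos)
    } else {
      ch <- ch[-(pos:min(pos + len - 1, length(ch)))]
    }
  }
  paste(ch, collapse = "")
}

rc <- function(x) as.character(seedasm::revcomp(x))

# Independent optimal local alignment score (Smith-Waterman with affine
# gaps) via Biostrings, matching the default nucleotide scoring scheme.
sw_oracle_score <- function(a, b, match = 1, mismatch = -2, gap_open = 5,
                            gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  as.numeric(Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)))
}

# Brute-force ungapped dovetail overlap detection: every offset, both
# orientations; reports maximal end-touching overlaps meeting the length
# and identity thresholds. Independent of the k-mer/banded implementation.
oracle_overlaps <- function(seqs, min_overlap = 40, min_identity = 0.83) {
  n <- length(seqs)
  out <- list()
  cmp1 <- function(a, b) {
    la <- nchar(a); lb <- nchar(b)
    av <- strsplit(a, "", fixed = TRUE)[[1]]
    bv <- strsplit(b, "", fixed = TRUE)[[1]]
    best <- NULL
    for (off in (-(lb - 1)):(la - 1)) {
      s_a <- max(0, off); e_a <- min(la, off + lb)
      len <- e_a - s_a
      if (len < min_overlap) next
      ia <- (s_a + 1):e_a
      ib <- ia - off
      m <- sum(av[ia] == bv[ib])
      if (m / len < min_identity) next
      if (is.null(best) || m > best$matches)
        best <- list(offset = off, length = len, matches = m,
                     identity = m / len)
    }
    best
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    for (orient in c("same", "reverse")) {
      b <- if (orient == "same") seqs[[j]] else rc(seqs[[j]])
      r <- cmp1(seqs[[i]], b)
      if (!is.null(r))
        out[[length(out) + 1L]] <- data.frame(
          i = i, j = j, orientation = orient, length = r$length,
          identity = r$identity, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(i = integer(0), j = integer(0), orientation = character(0),
               length = integer(0), identity = numeric(0))
}

# banded identity of a sequence to its source, in BLAST pident terms
ident_to_source <- function(seq, src, pad = 250) {
  sm <- seedasm:::scheme_submat(seedasm::scoring_scheme())
  r <- seedasm:::pair_align_cpp(seq, src, sm$mat, sm$alphabet, 5L, 2L,
                                -as.integer(pad), as.integer(pad), TRUE)
  if (!r$found || r$align_len == 0) return(0)
  r$n_match / r$align_len
}

# error-free tiling reads over a source, alternating orientations
tiling_reads <- function(src, read_len = 300, step = 150, flip_every = 3) {
  L <- nchar(src)
  starts <- seq(1, max(L - read_len + 1, 1), by = step)
  if (starts[length(starts)] + read_len - 1 < L)
    starts <- c(starts, L - read_len + 1)
  reads <- vapply(starts, function(s)
    substr(src, s, min(s + read_len - 1, L)), character(1))
  names(reads) <- paste0("t", seq_along(reads))
  if (flip_every > 0) {
    flip <- seq(2, length(reads), by = flip_every)
    reads[flip] <- vapply(reads[flip], rc, character(1))
  }
  reads
}

source_allele <- function(read_ids) sub(":.*", "", read_ids)
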