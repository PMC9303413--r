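# BLAST-like local search: nucleotide query vs nucleotide subjects, or
# protein query vs six-frame-translated subjects, with Karlin-Altschul
# bitscore/e-value statistics.

PROT_ALPHA <- "ARNDCQEGHILKMFPSTWYVBZ*X"  # X last: wildcard, never seeds

#' Scoring scheme for local alignment
#'
#' Holds the alignment scores and the Karlin-Altschul parameters used to
#' convert raw scores to bitscores and e-values. Defaults follow common
#' nucleotide-search practice: match +1, mismatch -2, gap open 5, gap extend
#' 2, with the published gapped lambda/K for that scheme; protein search uses
#' BLOSUM62 with gap 11/1.
#'
#' @param type `"nucleotide"` or `"protein"`.
#' @param match,mismatch Nucleotide match/mismatch scores (match > 0 >
#'   mismatch).
#' @param gap_open,gap_extend Positive gap penalties; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param lambda,K Karlin-Altschul parameters (both > 0).
#' @param protein_matrix Name of the protein matrix (only `"BLOSUM62"`).
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(type = c("nucleotide", "protein"),
                           match = 1L, mismatch = -2L,
                           gap_open = NULL, gap_extend = NULL,
                           lambda = NULL, K = NULL,
                           protein_matrix = "BLOSUM62") {
  type <- match.arg(type)
  if (type == "nucleotide") {
    if (is.null(gap_open)) gap_open <- 5L
    if (is.null(gap_extend)) gap_extend <- 2L
    if (is.null(lambda)) lambda <- 1.28
    if (is.null(K)) K <- 0.46
  } else {
    if (!identical(protein_matrix, "BLOSUM62"))
      stop("only BLOSUM62 is supported")
    if (is.null(gap_open)) gap_open <- 11L
    if (is.null(gap_extend)) gap_extend <- 1L
    if (is.null(lambda)) lambda <- 0.267
    if (is.null(K)) K <- 0.041
  }
  stopifnot(match > 0, mismatch < 0, gap_open > 0, gap_extend > 0,
            lambda > 0, K > 0)
  structure(list(type = type, match = as.integer(match),
                 mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K, protein_matrix = protein_matrix),
            class = "scoring_scheme")
}

# substitution matrix + alphabet string for the C++ kernels
scheme_submat <- function(scheme) {
  if (scheme$type == "nucleotide") {
    m <- matrix(scheme$mismatch, 5, 5)
    diag(m)[1:4] <- scheme$match
    m[5, ] <- scheme$mismatch; m[, 5] <- scheme$mismatch
    list(mat = m, alphabet = "ACGTN")
  } else {
    bl <- get_blosum62()
    letters <- strsplit(PROT_ALPHA, "")[[1]]
    m <- matrix(0L, length(letters), length(letters))
    for (i in seq_along(letters)) for (j in seq_along(letters)) {
      a <- letters[i]; b <- letters[j]
      m[i, j] <- if (a %in% rownames(bl) && b %in% colnames(bl))
        bl[a, b] else -1L
    }
    list(mat = m, alphabet = PROT_ALPHA)
  }
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Bitscore and e-value from a raw alignment score
#'
#' Karlin-Altschul statistics: bitscore `S' = (lambda * S - ln K) / ln 2`,
#' e-value `E = m * n * 2^(-S')`. E is monotone decreasing in S and doubles
#' when the database length doubles at fixed `S'`.
#'
#' @param raw_score Raw alignment score (>= 0).
#' @param m Query length (>= 1).
#' @param n Database length in bases/residues (>= 1).
#' @param scheme A [scoring_scheme()].
#' @return List with elements `bitscore` and `evalue` (vectorized).
#' @export
bitscore_evalue <- function(raw_score, m, n, scheme = scoring_scheme()) {
  stopifnot(all(raw_score >= 0), all(m >= 1), all(n >= 1))
  bits <- (scheme$lambda * raw_score - log(scheme$K)) / log(2)
  list(bitscore = bits, evalue = as.numeric(m) * as.numeric(n) * 2^(-bits))
}

#' Six-frame translation
#'
#' @param seq A nucleotide string (length >= 3). Frames -1..-3 are read from
#'   the reverse complement; trailing partial codons are dropped; stop codons
#'   appear as `*`, fuzzy codons as `X`.
#' @return Named character vector of the six translations
#'   (`"+1"`,`"+2"`,`"+3"`,`"-1"`,`"-2"`,`"-3"`).
#' @export
six_frame_translate <- function(seq) {
  if (is.list(seq)) seq <- seq$sequence
  if (nchar(seq) < 3L) stop("sequence shorter than one codon")
  fwd <- toupper(seq)
  rev <- as.character(revcomp(fwd))
  tr1 <- function(s, f) {
    sub <- substr(s, f, f + ((nchar(s) - f + 1L) %/% 3L) * 3L - 1L)
    if (nchar(sub) < 3L) return("")
    as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                       if.fuzzy.codon = "X"))
  }
  out <- c(tr1(fwd, 1L), tr1(fwd, 2L), tr1(fwd, 3L),
           tr1(rev, 1L), tr1(rev, 2L), tr1(rev, 3L))
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             bitscore = numeric(0), evalue = numeric(0),
             identity = numeric(0), align_len = integer(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             strand = character(0), frame = integer(0),
             score = integer(0), n_match = integer(0),
             path = character(0), stringsAsFactors = FALSE)
}

#' Seed-and-extend local alignment
#'
#' Shared exact k-mers (default k = 11 for nucleotide, k = 4 for translated
#' search) seed banded gapped extension. Nucleotide search extends every
#' seeded diagonal cluster (single-hit); translated search requires two
#' non-overlapping seeds on a cluster (two-hit rule) to tame the noise of
#' 4-mer protein seeds. Nucleotide queries are searched on both strands;
#' protein queries are
#' searched against all six reading frames of the subject. Hit coordinates
#' are 0-based half-open on the forward strand of each sequence.
#'
#' @param query A [seq_record()] or character scalar (non-empty).
#' @param subjects A list of [seq_record()], named character vector, or
#'   [read_store()].
#' @param scheme A [scoring_scheme()]; its `type` selects nucleotide or
#'   translated (protein-vs-nucleotide) search.
#' @param k Seed length; default 11 (nucleotide) or 4 (protein).
#' @param band_pad Extra diagonals allowed either side of the seeded band.
#' @param min_raw Raw-score cutoff below which hits are discarded.
#' @param two_hit Require two non-overlapping seeds on a diagonal cluster
#'   before extending. Default: off for nucleotide search (single-hit, as
#'   in standard nucleotide practice; needed for full sensitivity on short
#'   diverged matches), on for translated search.
#' @param db_len Database length for e-values; defaults to the total subject
#'   length.
#' @param want_path Keep the alignment path (needed for polishing pileups).
#' @return A data frame of hits sorted by decreasing bitscore, one row per
#'   high-scoring pair, with columns `query_id`, `subject_id`, `bitscore`,
#'   `evalue`, `identity`, `align_len`, `q_start`, `q_end`, `s_start`,
#'   `s_end`, `strand`, `frame`, `score`, `n_match`, `path`.
#' @export
align_local <- function(query, subjects, scheme = scoring_scheme(),
                        k = NULL, band_pad = 50L, min_raw = NULL,
                        db_len = NULL, want_path = FALSE,
                        two_hit = scheme$type == "protein") {
  qid <- if (inherits(query, "seq_record")) query$id else
    if (!is.null(names(query))) names(query)[1] else "query"
  qseq <- if (is.list(query)) query$sequence else as.character(query)
  if (!nzchar(qseq)) stop("empty query")
  if (inherits(subjects, "read_store")) {
    if (is.null(db_len)) db_len <- store_nbases(subjects)
    subjects <- store_get(subjects, store_ids(subjects))
  }
  sv <- as_named_seqs(subjects)
  if (is.null(db_len)) db_len <- sum(nchar(sv))
  if (is.null(k)) k <- if (scheme$type == "nucleotide") 11L else 4L
  if (is.null(min_raw))
    min_raw <- if (scheme$type == "nucleotide") 16L else 40L
  sm <- scheme_submat(scheme)

  if (scheme$type == "nucleotide") {
    res <- list(run_nuc_strand(qseq, sv, sm, scheme, k, band_pad, min_raw,
                               want_path, strand = "+", two_hit = two_hit),
                run_nuc_strand(qseq, sv, sm, scheme, k, band_pad, min_raw,
                               want_path, strand = "-", two_hit = two_hit))
    hits <- do.call(rbind, res)
  } else {
    hits <- run_tblastn(qseq, sv, sm, scheme, k, band_pad, min_raw,
                        want_path, two_hit)
  }
  if (is.null(hits) || nrow(hits) == 0L) return(empty_hits())
  hits$query_id <- qid
  be <- bitscore_evalue(hits$score, nchar(qseq), db_len, scheme)
  hits$bitscore <- be$bitscore
  hits$evalue <- be$evalue
  hits$identity <- hits$n_match / hits$align_len
  hits <- hits[order(-hits$bitscore, hits$subject_id, hits$s_start), ]
  rownames(hits) <- NULL
  hits[, names(empty_hits())]
}

# one nucleotide strand; '-' aligns revcomp(query) against forward subjects
# so paths stay in subject-forward coordinates
run_nuc_strand <- function(qseq, sv, sm, scheme, k, band_pad, min_raw,
                           want_path, strand, two_hit = FALSE) {
  q <- if (strand == "+") qseq else as.character(revcomp(qseq))
  lq <- nchar(qseq)
  keep <- nchar(sv) >= k
  if (!any(keep)) return(NULL)
  df <- search_hits_cpp(q, unname(sv[keep]), sm$mat, sm$alphabet, k,
                        scheme$gap_open, scheme$gap_extend, two_hit,
                        as.integer(band_pad), as.integer(min_raw), want_path)
  if (nrow(df) == 0L) return(NULL)
  df$subject_id <- names(sv[keep])[df$sidx]
  if (strand == "-") {
    qs <- lq - df$q_end
    qe <- lq - df$q_start
    df$q_start <- qs
    df$q_end <- qe
  }
  df$strand <- strand
  df$frame <- 0L
  df
}

run_tblastn <- function(qseq, sv, sm, scheme, k, band_pad, min_raw,
                        want_path, two_hit = TRUE) {
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  out <- list()
  for (i in seq_along(sv)) {
    L <- nchar(sv[[i]])
    if (L < 3L) next
    tr <- six_frame_translate(sv[[i]])
    keep <- nchar(tr) >= k
    if (!any(keep)) next
    df <- search_hits_cpp(qseq, unname(tr[keep]), sm$mat, sm$alphabet, k,
                          scheme$gap_open, scheme$gap_extend, two_hit,
                          as.integer(band_pad), as.integer(min_raw),
                          want_path)
    if (nrow(df) == 0L) next
    fr <- frames[keep][df$sidx]
    off <- abs(fr) - 1L
    nt_s <- ifelse(fr > 0, off + 3L * df$s_start, L - (off + 3L * df$s_end))
    nt_e <- ifelse(fr > 0, off + 3L * df$s_end, L - (off + 3L * df$s_start))
    df$s_start <- as.integer(nt_s)
    df$s_end <- as.integer(nt_e)
    df$subject_id <- names(sv)[i]
    df$strand <- ifelse(fr > 0, "+", "-")
    df$frame <- fr
    out[[length(out) + 1L]] <- df
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Rank reads by their best hit
#'
#' Overlapping hits on one subject collapse to the best-scoring one; ranking
#' is by decreasing bitscore with deterministic ties broken by subject id.
#'
#' @param hits A hit data frame from [align_local()] / [search_store()].
#' @return Data frame with columns `read_id`, `bitscore`, `evalue`.
#' @export
rank_reads <- function(hits) {
  if (nrow(hits) == 0L)
    return(data.frame(read_id = character(0), bitscore = numeric(0),
                      evalue = numeric(0), stringsAsFactors = FALSE))
  best <- do.call(rbind, lapply(split(hits, hits$subject_id), function(h)
    h[which.max(h$bitscore), c("subject_id", "bitscore", "evalue")]))
  best <- best[order(-best$bitscore, best$subject_id), ]
  rownames(best) <- NULL
  names(best)[1] <- "read_id"
  best
}

#' Search a read store with one or more queries
#'
#' Union over queries of [align_local()] hits with e-value at or below the
#' cutoff, capped at `max_hits` distinct subject reads kept in decreasing
#' best-bitscore order.
#'
#' @param queries List of [seq_record()] (or named character); must be
#'   non-empty.
#' @param store A [read_store()].
#' @param evalue_cutoff Keep hits with `evalue <= evalue_cutoff` (> 0).
#' @param max_hits Maximum number of distinct subject reads retained.
#' @param scheme A [scoring_scheme()].
#' @param ... Passed to [align_local()].
#' @return A hit data frame restricted to the retained reads, with the
#'   ranking as attribute `"ranked"` (a [rank_reads()] data frame).
#' @export
search_store <- function(queries, store, evalue_cutoff = 1e-10,
                         max_hits = 10000L, scheme = scoring_scheme(), ...) {
  if (is.character(queries)) queries <- as.list(as_named_seqs(queries))
  if (inherits(queries, "seq_record")) queries <- list(queries)
  if (length(queries) == 0L) stop("at least one query is required")
  stopifnot(evalue_cutoff > 0)
  all_hits <- list()
  for (i in seq_along(queries)) {
    q <- queries[[i]]
    if (is.character(q) && !is.null(names(queries)[i]) &&
        nzchar(names(queries)[i]) && is.null(names(q)))
      q <- setNames(q, names(queries)[i])
    h <- align_local(q, store, scheme = scheme, ...)
    h <- h[h$evalue <= evalue_cutoff, , drop = FALSE]
    if (nrow(h)) all_hits[[length(all_hits) + 1L]] <- h
  }
  hits <- if (length(all_hits)) do.call(rbind, all_hits) else empty_hits()
  ranked <- rank_reads(hits)
  if (nrow(ranked) > max_hits) {
    ranked <- ranked[seq_len(max_hits), ]
    hits <- hits[hits$subject_id %in% ranked$read_id, , drop = FALSE]
  }
  rownames(hits) <- NULL
  attr(hits, "ranked") <- ranked
  hits
}

#' Write hits as tab-separated text in BLAST outfmt-6 column order
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore, with 1-based inclusive coordinates.
#'
#' @param hits A hit data frame.
#' @param path Output path (or "" for stdout).
#' @return `path` invisibly.
#' @export
write_hits_tsv <- function(hits, path = "") {
  gapinfo <- vapply(hits$path, function(p) {
    if (!nzchar(p)) return(c(NA_integer_, NA_integer_))
    ch <- strsplit(p, "")[[1]]
    r <- rle(ch)
    c(sum(ch %in% c("I", "D")), sum(r$values %in% c("I", "D")))
  }, integer(2))
  gapcols <- gapinfo[1, ]; gapruns <- gapinfo[2, ]
  out <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = round(100 * hits$identity, 3), length = hits$align_len,
    mismatch = hits$align_len - hits$n_match -
      ifelse(is.na(gapcols), 0L, gapcols),
    gapopen = ifelse(is.na(gapruns), 0L, gapruns),
    qstart = hits$q_start + 1L, qend = hits$q_end,
    sstart = ifelse(hits$strand == "+", hits$s_start + 1L, hits$s_end),
    send = ifelse(hits$strand == "+", hits$s_end, hits$s_start + 1L),
    evalue = signif(hits$evalue, 3), bitscore = round(hits$bitscore, 1),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
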