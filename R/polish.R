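# Pileup-majority polishing of contigs with accurate short reads.

# Expand one alignment path into per-column votes in contig coordinates.
# Returns list(cpos, sym, wt) for columns and list(jpos, str) for insertions.
expand_path_votes <- function(hit, read_seq, read_qual = NULL) {
  opv <- strsplit(hit$path, "", fixed = TRUE)[[1]]
  if (!length(opv)) return(NULL)
  cpos <- hit$q_start + cumsum(opv != "I")
  rpos <- hit$s_start + cumsum(opv != "D")
  rch <- strsplit(read_seq, "", fixed = TRUE)[[1]]
  isM <- opv == "M"; isD <- opv == "D"; isI <- opv == "I"
  sym <- character(length(opv))
  sym[isM] <- rch[rpos[isM]]
  sym[isD] <- "-"
  wt <- rep(1, length(opv))
  if (!is.null(read_qual)) {
    q <- read_qual[pmin(pmax(rpos, 1L), length(read_qual))]
    wt <- pmax(q, 1)
  }
  ins <- NULL
  if (any(isI)) {
    # consecutive I ops at one junction form one inserted string
    jpos <- cpos[isI]                       # junction: after contig col jpos
    grp <- cumsum(c(TRUE, diff(which(isI)) != 1L))
    ins <- data.frame(jpos = tapply(jpos, grp, `[`, 1L),
                      str = tapply(rch[rpos[isI]], grp, paste, collapse = ""),
                      stringsAsFactors = FALSE)
  }
  list(cpos = cpos[!isI], sym = sym[!isI], wt = wt[!isI],
       span = c(hit$q_start, hit$q_end), ins = ins)
}

#' Polish a contig by pileup majority vote
#'
#' Each iteration aligns the polishing reads to the contig with the
#' seed-and-extend aligner, builds a pileup, and replaces every column of
#' depth at least `min_depth` by the weighted majority among
#' `{A,C,G,T,N,deletion}`; insertions reported by a majority of the spanning
#' reads are applied between columns. Columns below `min_depth` are never
#' changed. Qualities, when present on the reads, weight the votes.
#'
#' @param contig A `contig` object (or [seq_record()]).
#' @param reads A [read_store()] or list of [seq_record()] with the accurate
#'   (short) reads.
#' @param iterations Number of polishing iterations (>= 0); 0 returns the
#'   input unchanged. The customary maximum is 5.
#' @param min_depth Minimum pileup depth for a column to be editable
#'   (default 2).
#' @param scheme Nucleotide [scoring_scheme()] used for the read alignments.
#' @param min_raw Raw-score cutoff for accepted read alignments.
#' @return The polished contig; its id gains a `.polN` suffix recording the
#'   iterations applied. If no reads align, the contig is returned unchanged
#'   with a warning.
#' @export
polish <- function(contig, reads, iterations = 1L, min_depth = 2L,
                   scheme = scoring_scheme(), min_raw = 30L) {
  stopifnot(iterations >= 0L)
  if (inherits(contig, "seq_record"))
    contig <- structure(list(id = contig$id, sequence = contig$sequence,
                             layout = data.frame(), depth = integer(0),
                             n_reads = NA_integer_), class = "contig")
  if (iterations == 0L) return(contig)
  if (inherits(reads, "read_store")) reads <- store_get(reads,
                                                        store_ids(reads))
  sv <- as_named_seqs(reads)
  quals <- lapply(reads, function(r)
    if (is.list(r)) r$qualities else NULL)
  names(quals) <- names(sv)

  seqnow <- contig$sequence
  for (iter in seq_len(iterations)) {
    res <- polish_once(seqnow, sv, quals, min_depth, scheme, min_raw)
    if (is.null(res)) {
      warning("no reads aligned to contig ", contig$id,
              "; returned unchanged")
      break
    }
    seqnow <- res$seq
    contig$depth <- res$depth
  }
  contig$sequence <- seqnow
  contig$id <- paste0(contig$id, ".pol", iterations)
  contig
}

polish_once <- function(contig_seq, sv, quals, min_depth, scheme, min_raw) {
  sm <- scheme_submat(scheme)
  L <- nchar(contig_seq)
  subjects <- c(unname(sv), as.character(revcomp(unname(sv))))
  df <- search_hits_cpp(contig_seq, subjects, sm$mat, sm$alphabet, 11L,
                        scheme$gap_open, scheme$gap_extend, FALSE, 30L,
                        as.integer(min_raw), TRUE)
  if (nrow(df) == 0L) return(NULL)
  n <- length(sv)
  df$ridx <- ifelse(df$sidx > n, df$sidx - n, df$sidx)
  df$rc <- df$sidx > n
  # best alignment per read, forward preferred on ties
  df <- df[order(-df$score, df$ridx, df$rc), ]
  df <- df[!duplicated(df$ridx), , drop = FALSE]

  votes_pos <- vector("list", nrow(df))
  votes_sym <- vector("list", nrow(df))
  votes_wt <- vector("list", nrow(df))
  cov_start <- integer(nrow(df)); cov_end <- integer(nrow(df))
  ins_all <- list()
  for (t in seq_len(nrow(df))) {
    h <- df[t, ]
    rseq <- subjects[h$sidx]
    rq <- quals[[h$ridx]]
    if (h$rc && !is.null(rq)) rq <- rev(rq)
    ev <- expand_path_votes(h, rseq, rq)
    if (is.null(ev)) next
    votes_pos[[t]] <- ev$cpos; votes_sym[[t]] <- ev$sym
    votes_wt[[t]] <- ev$wt
    cov_start[t] <- ev$span[1]; cov_end[t] <- ev$span[2]
    if (!is.null(ev$ins)) ins_all[[length(ins_all) + 1L]] <- ev$ins
  }
  pos <- unlist(votes_pos); sym <- unlist(votes_sym); wt <- unlist(votes_wt)
  if (!length(pos)) return(NULL)

  # weighted votes per (column, symbol) and unweighted depth per column
  si <- match(sym, BASE_ORDER)
  key <- (pos - 1L) * 6L + si
  wsum <- rowsum(wt, key)
  kv <- as.integer(rownames(wsum))
  vmat <- matrix(0, nrow = L, ncol = 6L)
  vmat[cbind((kv - 1L) %/% 6L + 1L, (kv - 1L) %% 6L + 1L)] <- wsum[, 1L]
  depth <- tabulate(pos, nbins = L)

  win <- max.col(vmat, ties.method = "first")  # BASE_ORDER order = priority
  editable <- depth >= min_depth
  orig <- strsplit(contig_seq, "", fixed = TRUE)[[1]]
  newb <- ifelse(editable, BASE_ORDER[win], orig)

  # majority insertions at junctions (after contig column j, 0..L)
  ins_by_j <- list()
  if (length(ins_all)) {
    insdf <- do.call(rbind, ins_all)
    # spanning depth at junction j = reads covering columns j and j+1
    covers <- function(j) sum(cov_start < j & cov_end > j)
    agg <- stats::aggregate(rep(1L, nrow(insdf)),
                            by = list(jpos = insdf$jpos, str = insdf$str),
                            FUN = sum)
    for (j in unique(agg$jpos)) {
      a <- agg[agg$jpos == j, , drop = FALSE]
      a <- a[order(-a$x, a$str), , drop = FALSE]
      spanning <- covers(j)
      if (spanning >= min_depth && 2L * a$x[1L] > spanning)
        ins_by_j[[as.character(j)]] <- a$str[1L]
    }
  }

  keepb <- newb != "-"
  pieces <- character(0)
  jkeys <- as.integer(names(ins_by_j))
  out_depth <- integer(0)
  if (length(ins_by_j)) {
    # assemble sequence with insertions at recorded junctions
    res <- character(L + length(ins_by_j))
    lastj <- 0L
    buf <- list()
    ord <- order(jkeys)
    prev <- 0L
    for (oi in seq_along(ord)) {
      j <- jkeys[ord[oi]]
      seg <- if (j >= prev + 1L) which(seq_len(L) > prev & seq_len(L) <= j)
             else integer(0)
      buf[[length(buf) + 1L]] <- paste(newb[seg][keepb[seg]], collapse = "")
      buf[[length(buf) + 1L]] <- ins_by_j[[as.character(j)]]
      prev <- j
    }
    seg <- which(seq_len(L) > prev)
    buf[[length(buf) + 1L]] <- paste(newb[seg][keepb[seg]], collapse = "")
    newseq <- paste(unlist(buf), collapse = "")
  } else {
    newseq <- paste(newb[keepb], collapse = "")
  }
  if (!nzchar(newseq)) return(NULL)
  list(seq = newseq, depth = depth)
}
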