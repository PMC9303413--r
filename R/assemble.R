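# Built-in greedy overlap-layout-consensus assembler, plus the contract for
# plugging in an external assembler.

BASE_ORDER <- c("A", "C", "G", "T", "N", "-")

#' Assembler tunables
#'
#' Mirrors the knobs of classical overlap assemblers: minimum overlap length
#' and identity for an accepted join (defaults 40 and 0.83; 0.93 or 0.97 are
#' the usual stricter alternatives when distinct alleles must stay separate),
#' and the match/mismatch/gap scores used to score overlaps.
#'
#' @param min_overlap Minimum accepted overlap length (>= 10; default 40).
#' @param min_identity Minimum accepted overlap identity (0 < x <= 1;
#'   default 0.83).
#' @param match,mismatch,gap Overlap scoring (gap is a positive per-base
#'   penalty).
#' @param keep_singletons Report unassembled reads as one-read contigs
#'   (default FALSE).
#' @param kmer Seed length for overlap candidate detection.
#' @param band_pad Diagonal slack around seeded overlap bands.
#' @return An object of class `assembler_params`.
#' @export
assembler_params <- function(min_overlap = 40L, min_identity = 0.83,
                             match = 2L, mismatch = -4L, gap = 5L,
                             keep_singletons = FALSE, kmer = 12L,
                             band_pad = 40L) {
  stopifnot(min_overlap >= 10L, min_identity > 0, min_identity <= 1,
            match > 0, mismatch < 0, gap > 0)
  structure(list(min_overlap = as.integer(min_overlap),
                 min_identity = min_identity, match = as.integer(match),
                 mismatch = as.integer(mismatch), gap = as.integer(gap),
                 keep_singletons = isTRUE(keep_singletons),
                 kmer = as.integer(kmer), band_pad = as.integer(band_pad)),
            class = "assembler_params")
}

#' Weighted-majority consensus call for one column
#'
#' @param bases Character vector of column symbols (`A,C,G,T,N` and `-` for a
#'   deletion vote).
#' @param weights Optional numeric weights (e.g. qualities); default 1 each.
#' @return The winning symbol; ties break by the fixed order `A<C<G<T<N<-`.
#' @export
consensus_base <- function(bases, weights = NULL) {
  stopifnot(length(bases) > 0)
  if (is.null(weights)) weights <- rep(1, length(bases))
  tot <- vapply(BASE_ORDER, function(b) sum(weights[bases == b]), numeric(1))
  BASE_ORDER[which.max(tot)]
}

#' Find pairwise dovetail overlaps among reads
#'
#' Candidate pairs share an exact k-mer (either orientation); each candidate
#' is aligned with banded ends-free dynamic programming. An overlap is
#' accepted when it touches an end of each read (containment included), is at
#' least `min_overlap` long and at least `min_identity` identical.
#'
#' @param reads List of [seq_record()] or named character vector (>= 2).
#' @param params An [assembler_params()].
#' @return Data frame of overlaps, ordered by decreasing score then id pair:
#'   `read_a`, `read_b`, `orientation` (`same`/`reverse`; coordinates of
#'   `read_b` refer to its reverse complement when `reverse`), `a_start`,
#'   `a_end`, `b_start`, `b_end` (0-based half-open), `length`, `identity`,
#'   `score`, `path`.
#' @export
find_overlaps <- function(reads, params = assembler_params()) {
  sv <- as_named_seqs(reads)
  if (length(sv) < 2L) stop("need at least two reads")
  df <- overlap_pairs_cpp(unname(sv), params$kmer, params$min_overlap,
                          params$min_identity, params$match,
                          params$mismatch, 0L, params$gap, params$band_pad)
  df$read_a <- names(sv)[df$i]
  df$read_b <- names(sv)[df$j]
  df <- df[order(-df$score, df$read_a, df$read_b, df$orientation), ]
  rownames(df) <- NULL
  df[, c("read_a", "read_b", "orientation", "a_start", "a_end", "b_start",
         "b_end", "length", "identity", "n_match", "score", "path", "i",
         "j")]
}

new_assembly <- function(id, sequence, qualities = NULL) {
  n <- nchar(sequence)
  list(seq = sequence, depth = rep(1L, n),
       layout = data.frame(read_id = id, start = 0L, end = n,
                           orient = "+", stringsAsFactors = FALSE))
}

flip_assembly <- function(a) {
  L <- nchar(a$seq)
  lay <- a$layout
  lay$orient <- ifelse(lay$orient == "+", "-", "+")
  ns <- L - lay$end
  ne <- L - lay$start
  lay$start <- ns
  lay$end <- ne
  list(seq = as.character(revcomp(a$seq)), depth = rev(a$depth),
       layout = lay)
}

# next-kept fill for coordinate maps (dropped columns map to the next kept
# merged position; trailing NAs map one past the end)
fill_map <- function(m, total) {
  nas <- which(is.na(m))
  if (length(nas)) {
    for (i in rev(nas)) m[i] <- if (i == length(m)) total + 1L else m[i + 1L]
  }
  m
}

# Merge two assemblies along an accepted overlap alignment. `ov` is one row
# of an overlap table whose coordinates refer to a (=A) and to B in the
# orientation given; B must already be flipped by the caller when reverse.
splice_assemblies <- function(A, B, ov) {
  la <- nchar(A$seq); lb <- nchar(B$seq)
  Ach <- strsplit(A$seq, "", fixed = TRUE)[[1]]
  Bch <- strsplit(B$seq, "", fixed = TRUE)[[1]]
  opv <- strsplit(ov$path, "", fixed = TRUE)[[1]]
  aidx <- ov$a_start + cumsum(opv != "I")  # 1-based A pos consumed (M/D)
  bidx <- ov$b_start + cumsum(opv != "D")
  isM <- opv == "M"; isD <- opv == "D"; isI <- opv == "I"
  wa <- A$depth[pmin(pmax(aidx, 1L), la)]
  wb <- B$depth[pmin(pmax(bidx, 1L), lb)]

  keep <- logical(length(opv))
  keep[isM] <- TRUE
  keep[isD] <- wa[isD] >= wb[isD]          # deletion votes from B
  keep[isI] <- wb[isI] > wa[isI]           # insertion votes from B
  ab <- Ach[aidx]; bb <- Bch[bidx]
  colbase <- character(length(opv))
  fA <- match(ab, BASE_ORDER); fB <- match(bb, BASE_ORDER)
  pick_b <- (wb > wa) | (wb == wa & fB < fA)
  colbase[isM] <- ifelse(ab[isM] == bb[isM], ab[isM],
                         ifelse(pick_b[isM], bb[isM], ab[isM]))
  colbase[isD] <- ab[isD]
  colbase[isI] <- bb[isI]
  coldepth <- integer(length(opv))
  coldepth[isM] <- wa[isM] + wb[isM]
  coldepth[isD] <- wa[isD]
  coldepth[isI] <- wb[isI]

  mapA <- rep(NA_integer_, la)
  mapB <- rep(NA_integer_, lb)
  chunks_ch <- list(); chunks_d <- list()
  pos <- 0L
  if (ov$a_start > 0L) {
    mapA[seq_len(ov$a_start)] <- seq_len(ov$a_start)
    chunks_ch[[1]] <- Ach[seq_len(ov$a_start)]
    chunks_d[[1]] <- A$depth[seq_len(ov$a_start)]
    pos <- ov$a_start
  } else if (ov$b_start > 0L) {
    mapB[seq_len(ov$b_start)] <- seq_len(ov$b_start)
    chunks_ch[[1]] <- Bch[seq_len(ov$b_start)]
    chunks_d[[1]] <- B$depth[seq_len(ov$b_start)]
    pos <- ov$b_start
  }
  newpos <- rep(NA_integer_, length(opv))
  newpos[keep] <- pos + seq_len(sum(keep))
  ka <- keep & !isI
  mapA[aidx[ka]] <- newpos[ka]
  kb <- keep & !isD
  mapB[bidx[kb]] <- newpos[kb]
  chunks_ch[[length(chunks_ch) + 1L]] <- colbase[keep]
  chunks_d[[length(chunks_d) + 1L]] <- coldepth[keep]
  pos <- pos + sum(keep)
  if (ov$a_end < la) {
    idx <- (ov$a_end + 1L):la
    mapA[idx] <- pos + seq_along(idx)
    chunks_ch[[length(chunks_ch) + 1L]] <- Ach[idx]
    chunks_d[[length(chunks_d) + 1L]] <- A$depth[idx]
    pos <- pos + length(idx)
  }
  if (ov$b_end < lb) {
    idx <- (ov$b_end + 1L):lb
    mapB[idx] <- pos + seq_along(idx)
    chunks_ch[[length(chunks_ch) + 1L]] <- Bch[idx]
    chunks_d[[length(chunks_d) + 1L]] <- B$depth[idx]
    pos <- pos + length(idx)
  }
  total <- pos
  mapA <- fill_map(mapA, total)
  mapB <- fill_map(mapB, total)

  layA <- A$layout
  layA$start <- pmin(mapA[layA$start + 1L] - 1L, total - 1L)
  layA$end <- pmin(pmax(mapA[layA$end], layA$start + 1L), total)
  layB <- B$layout
  layB$start <- pmin(mapB[layB$start + 1L] - 1L, total - 1L)
  layB$end <- pmin(pmax(mapB[layB$end], layB$start + 1L), total)

  list(seq = paste(unlist(chunks_ch), collapse = ""),
       depth = unlist(chunks_d),
       layout = rbind(layA, layB))
}

# Max-heap of edge-pool indices. Priority: score desc, then smaller ia,
# smaller ja, orientation ("reverse" before "same") for determinism.
edge_heap <- function(pool) {
  H <- new.env(parent = emptyenv())
  H$h <- integer(0)
  H$pool <- pool
  H
}

edge_before <- function(p, a, b) {
  if (p$score[a] != p$score[b]) return(p$score[a] > p$score[b])
  if (p$ia[a] != p$ia[b]) return(p$ia[a] < p$ia[b])
  if (p$ja[a] != p$ja[b]) return(p$ja[a] < p$ja[b])
  p$orientation[a] <= p$orientation[b]
}

heap_push <- function(H, k) {
  h <- H$h
  h[length(h) + 1L] <- k
  i <- length(h)
  while (i > 1L) {
    par <- i %/% 2L
    if (edge_before(H$pool, h[i], h[par])) {
      tmp <- h[par]; h[par] <- h[i]; h[i] <- tmp
      i <- par
    } else break
  }
  H$h <- h
}

heap_pop <- function(H) {
  h <- H$h
  if (!length(h)) return(NA_integer_)
  top <- h[1L]
  h[1L] <- h[length(h)]
  h <- h[-length(h)]
  i <- 1L
  n <- length(h)
  while (TRUE) {
    l <- 2L * i; r <- l + 1L
    m <- i
    if (l <= n && edge_before(H$pool, h[l], h[m])) m <- l
    if (r <= n && edge_before(H$pool, h[r], h[m])) m <- r
    if (m == i) break
    tmp <- h[m]; h[m] <- h[i]; h[i] <- tmp
    i <- m
  }
  H$h <- h
  top
}

pool_env <- function() {
  p <- new.env(parent = emptyenv())
  p$n <- 0L
  for (f in c("ia", "ja", "a_start", "a_end", "b_start", "b_end",
              "length", "n_match"))
    assign(f, integer(0), envir = p)
  p$score <- integer(0)
  p$identity <- numeric(0)
  p$orientation <- character(0)
  p$path <- character(0)
  p
}

pool_add <- function(p, ia, ja, d) {
  k <- p$n + seq_along(ia)
  p$n <- p$n + length(ia)
  p$ia[k] <- ia; p$ja[k] <- ja
  p$orientation[k] <- d$orientation
  p$score[k] <- d$score
  p$a_start[k] <- d$a_start; p$a_end[k] <- d$a_end
  p$b_start[k] <- d$b_start; p$b_end[k] <- d$b_end
  p$length[k] <- d$length; p$identity[k] <- d$identity
  p$n_match[k] <- d$n_match
  p$path[k] <- d$path
  k
}

pool_edge <- function(p, k) {
  list(ia = p$ia[k], ja = p$ja[k], orientation = p$orientation[k],
       score = p$score[k], a_start = p$a_start[k], a_end = p$a_end[k],
       b_start = p$b_start[k], b_end = p$b_end[k], length = p$length[k],
       identity = p$identity[k], n_match = p$n_match[k], path = p$path[k])
}

#' Greedy overlap-layout-consensus assembly
#'
#' Repeatedly merges the highest-scoring remaining overlap between current
#' assemblies (reads or growing contigs), recomputing the consensus after
#' each merge by depth-weighted column votes, until no overlap passing
#' `min_overlap`/`min_identity` remains. Each read receives a canonical
#' orientation at first placement; a contig is reported in the orientation
#' of its first-placed read.
#'
#' @param reads List of [seq_record()] or named character vector (non-empty).
#' @param params An [assembler_params()].
#' @return List of `contig` objects, ids `c1..cN` in decreasing length. Each
#'   contig has `id`, `sequence`, `layout` (read_id, contig_start,
#'   contig_end, orientation), `depth` (per-column read count) and `n_reads`.
#'   Singletons are dropped unless `keep_singletons`.
#' @export
greedy_assemble <- function(reads, params = assembler_params()) {
  sv <- as_named_seqs(reads)
  if (length(sv) == 0L) stop("no reads to assemble")
  if (anyDuplicated(names(sv))) stop("duplicate read ids")
  assemblies <- lapply(seq_along(sv), function(i)
    new_assembly(names(sv)[i], sv[[i]]))
  active <- rep(TRUE, length(sv))
  repr <- seq_along(sv)           # union-find: assembly -> current holder
  find_repr <- function(x) {
    while (repr[x] != x) x <- repr[x]
    x
  }

  pool <- pool_env()
  H <- edge_heap(pool)
  checked <- new.env(hash = TRUE, parent = emptyenv())

  if (length(sv) >= 2L) {
    d <- overlap_pairs_cpp(unname(sv), params$kmer, params$min_overlap,
                           params$min_identity, params$match,
                           params$mismatch, 0L, params$gap, params$band_pad)
    if (nrow(d))
      for (k in pool_add(pool, d$i, d$j, d)) heap_push(H, k)
  }

  merge_edge <- function(e) {
    A <- assemblies[[e$ia]]
    B <- assemblies[[e$ja]]
    if (e$orientation == "reverse") B <- flip_assembly(B)
    merged <- splice_assemblies(A, B, e)
    assemblies[[length(assemblies) + 1L]] <<- merged
    m <- length(assemblies)
    active[e$ia] <<- FALSE; active[e$ja] <<- FALSE
    active <<- c(active, TRUE)
    repr[e$ia] <<- m; repr[e$ja] <<- m; repr[m] <<- m
    m
  }

  # lazy-revalidation greedy: stale edges (an endpoint already merged away)
  # are re-aligned against the endpoints' current assemblies when they
  # surface at the top of the heap
  repeat {
    k <- heap_pop(H)
    if (is.na(k)) break
    e <- pool_edge(pool, k)
    ri <- find_repr(e$ia); rj <- find_repr(e$ja)
    if (ri == rj) next
    if (ri == e$ia && rj == e$ja) {
      merge_edge(e)
      next
    }
    a <- min(ri, rj); b <- max(ri, rj)
    key <- paste0(a, ":", b)
    if (!is.null(checked[[key]])) next
    checked[[key]] <- TRUE
    d <- overlaps_vs_cpp(assemblies[[a]]$seq, assemblies[[b]]$seq,
                         params$kmer, params$min_overlap,
                         params$min_identity, params$match,
                         params$mismatch, 0L, params$gap, params$band_pad)
    if (nrow(d)) {
      d <- d[order(-d$score, d$orientation), , drop = FALSE][1L, ,
                                                             drop = FALSE]
      heap_push(H, pool_add(pool, a, b, d))
    }
  }

  # closure sweep at the contig level: eager re-detection among survivors
  repeat {
    idx <- which(active)
    if (length(idx) < 2L) break
    d <- overlap_pairs_cpp(vapply(assemblies[idx], `[[`, character(1),
                                  "seq"),
                           params$kmer, params$min_overlap,
                           params$min_identity, params$match,
                           params$mismatch, 0L, params$gap, params$band_pad)
    if (nrow(d) == 0L) break
    d <- d[order(-d$score, d$i, d$j, d$orientation), , drop = FALSE]
    e <- pool_edge(pool, pool_add(pool, idx[d$i[1L]], idx[d$j[1L]],
                                  d[1L, , drop = FALSE]))
    merge_edge(e)
  }

  out <- assemblies[active]
  nread <- vapply(out, function(a) nrow(a$layout), integer(1))
  if (!params$keep_singletons) out <- out[nread > 1L]
  if (length(out) == 0L) return(list())
  lens <- vapply(out, function(a) nchar(a$seq), integer(1))
  out <- out[order(-lens, vapply(out, function(a) a$layout$read_id[1],
                                 character(1)))]
  lapply(seq_along(out), function(i) {
    a <- out[[i]]
    structure(list(id = paste0("c", i), sequence = a$seq,
                   layout = data.frame(read_id = a$layout$read_id,
                                       contig_start = a$layout$start,
                                       contig_end = a$layout$end,
                                       orientation = a$layout$orient,
                                       stringsAsFactors = FALSE),
                   depth = a$depth, n_reads = nrow(a$layout)),
              class = "contig")
  })
}

#' @export
print.contig <- function(x, ...) {
  cat("<contig> ", x$id, ": ", nchar(x$sequence), " bases from ", x$n_reads,
      " reads, mean depth ", round(mean(x$depth), 2), "\n", sep = "")
  invisible(x)
}

#' Parse an external assembler's contig FASTA into contig objects
#'
#' Layout and depth are left empty: an external tool reports only consensus
#' sequences.
#'
#' @param path Contig FASTA file.
#' @return List of `contig` objects.
#' @export
parse_contig_fasta <- function(path) {
  recs <- read_fasta(path)
  lapply(recs, function(r)
    structure(list(id = r$id, sequence = r$sequence,
                   layout = data.frame(read_id = character(0),
                                       contig_start = integer(0),
                                       contig_end = integer(0),
                                       orientation = character(0),
                                       stringsAsFactors = FALSE),
                   depth = integer(0), n_reads = NA_integer_),
              class = "contig"))
}

#' Run an external assembler (adapter contract)
#'
#' Writes the reads to a temporary FASTA, substitutes `{reads}` and `{out}`
#' into the command template, runs it, and parses the output contig FASTA.
#' The executable is never required by this package; when it is absent a
#' descriptive error advises the built-in assembler.
#'
#' @param reads List of [seq_record()] or named character vector.
#' @param tool_spec List with `name` (executable), `command` (template with
#'   `{reads}` and `{out}` placeholders) and optionally `parse` (function
#'   from output path to contigs; default [parse_contig_fasta()]).
#' @return List of `contig` objects.
#' @export
external_assembler <- function(reads, tool_spec) {
  stopifnot(is.list(tool_spec), !is.null(tool_spec$name),
            !is.null(tool_spec$command))
  if (!nzchar(Sys.which(tool_spec$name)))
    stop("external assembler '", tool_spec$name, "' not found on PATH; ",
         "use the built-in greedy assembler (assembler = \"builtin\") ",
         "or install the tool")
  reads_fa <- tempfile(fileext = ".fasta")
  out_fa <- tempfile(fileext = ".fasta")
  write_fasta(reads, reads_fa)
  cmd <- gsub("{reads}", reads_fa,
              gsub("{out}", out_fa, tool_spec$command, fixed = TRUE),
              fixed = TRUE)
  status <- system(cmd)
  if (status != 0L) stop("external assembler exited with status ", status)
  parse <- if (is.null(tool_spec$parse)) parse_contig_fasta else
    tool_spec$parse
  parse(out_fa)
}
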