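# FASTA/FASTQ input and output and the in-memory indexed read store.

NUC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Create a sequence record
#'
#' The atomic unit handled by the read store, the aligner and the assembler.
#'
#' @param id Record identifier; must be non-empty and unique within a store.
#' @param sequence Character scalar over the nucleotide or amino-acid
#'   alphabet. Stored uppercased.
#' @param qualities Optional integer vector of per-base Phred scores, same
#'   length as `sequence`.
#' @param mate_of Optional id of the paired-end mate.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, sequence, qualities = NULL, mate_of = NULL) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("record id must be a non-empty string")
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("record '", id, "' has an empty sequence")
  if (!is.null(qualities) && length(qualities) != nchar(sequence))
    stop("record '", id, "': qualities length differs from sequence length")
  structure(list(id = id, sequence = sequence, qualities = qualities,
                 mate_of = mate_of),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat("<seq_record> ", x$id, " (", nchar(x$sequence), " bases",
      if (!is.null(x$mate_of)) paste0(", mate of ", x$mate_of), ")\n",
      sep = "")
  invisible(x)
}

# Uppercase, U->T, and (for nucleotide input) collapse IUPAC ambiguity codes
# other than N to N with a warning. `alphabet` "auto" treats sequences whose
# characters are >=90% ACGTUN- as nucleotide.
clean_sequence <- function(x, alphabet = c("auto", "nucleotide", "protein"),
                           what = "sequence") {
  alphabet <- match.arg(alphabet)
  x <- toupper(x)
  if (alphabet == "auto") {
    ch <- strsplit(paste(x, collapse = ""), "", fixed = TRUE)[[1]]
    frac <- mean(ch %in% c("A", "C", "G", "T", "U", "N"))
    alphabet <- if (frac >= 0.9) "nucleotide" else "protein"
  }
  if (alphabet == "nucleotide") {
    x <- gsub("U", "T", x, fixed = TRUE)
    if (any(grepl(paste0("[", paste(NUC_AMBIG, collapse = ""), "]"), x))) {
      warning("ambiguity codes other than N replaced by N in ", what)
      x <- chartr(paste(NUC_AMBIG, collapse = ""),
                  strrep("N", length(NUC_AMBIG)), x)
    }
    bad <- grepl("[^ACGTN]", x)
    if (any(bad)) {
      warning("non-IUPAC characters replaced by N in ", what)
      x[bad] <- vapply(x[bad], function(s) {
        ch <- strsplit(s, "", fixed = TRUE)[[1]]
        ch[!ch %in% c("A", "C", "G", "T", "N")] <- "N"
        paste(ch, collapse = "")
      }, character(1))
    }
  }
  attr(x, "alphabet") <- alphabet
  x
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"auto"` (default), `"nucleotide"` or `"protein"`.
#'   Nucleotide sequences are uppercased, `U` becomes `T`, and ambiguity
#'   codes other than `N` become `N` with a warning.
#' @return A list of [seq_record()] objects, one per header. The record id is
#'   the first whitespace-delimited token of the header.
#' @export
read_fasta <- function(path, alphabet = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) return(list())
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L])
    stop("FASTA parse error at line ", lineno[1L],
         ": expected '>' header, got sequence")
  hdr_idx <- which(is_hdr)
  ids <- vapply(lines[hdr_idx], function(h)
    strsplit(trimws(sub("^>", "", h)), "\\s+")[[1]][1], character(1),
    USE.NAMES = FALSE)
  if (anyNA(ids) || any(!nzchar(ids))) {
    bad <- which(is.na(ids) | !nzchar(ids))[1L]
    stop("FASTA parse error at line ", lineno[hdr_idx[bad]],
         ": empty header")
  }
  grp <- cumsum(is_hdr)
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]), function(x)
    gsub("\\s", "", paste(x, collapse = "")), character(1))
  seqs_full <- setNames(character(length(hdr_idx)), seq_along(hdr_idx))
  seqs_full[names(seqs)] <- seqs
  empty <- !nzchar(seqs_full)
  if (any(empty)) {
    bad <- which(empty)[1L]
    stop("FASTA parse error at line ", lineno[hdr_idx[bad]],
         ": record '", ids[bad], "' has no sequence")
  }
  cleaned <- clean_sequence(unname(seqs_full), alphabet,
                            what = basename(path))
  recs <- mapply(function(id, s) seq_record(id, s), ids, cleaned,
                 SIMPLIFY = FALSE, USE.NAMES = FALSE)
  names(recs) <- ids
  recs
}

# strip trailing /1, /2 or Illumina-style " 1:N:..." mate decorations
strip_mate_suffix <- function(id) {
  sub("/[12]$", "", sub("\\s+[12]:.*$", "", id))
}

parse_fastq_lines <- function(lines, path, offset) {
  keep <- nzchar(lines)
  lines <- lines[keep]
  if (length(lines) %% 4L != 0L)
    stop("FASTQ parse error in ", path, ": line count ", length(lines),
         " is not a multiple of 4")
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  quals <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop("FASTQ parse error at record ", bad[1L], " in ", path,
         ": header does not start with '@'")
  mism <- which(nchar(seqs) != nchar(quals))
  if (length(mism))
    stop("FASTQ parse error at record ", mism[1L], " in ", path,
         ": sequence and quality lengths differ")
  ids <- vapply(strsplit(sub("^@", "", hdr), "\\s+"), `[[`, character(1), 1L)
  list(ids = ids, hdr = sub("^@", "", hdr),
       seqs = clean_sequence(seqs, "nucleotide", what = basename(path)),
       quals = lapply(quals, function(q) utf8ToInt(q) - offset))
}

#' Read a FASTQ file (optionally a read pair)
#'
#' Supports single files, interleaved pairs and two-file pairs. Mates are
#' linked through `mate_of` after stripping trailing `/1`, `/2` or
#' Illumina-style ` 1:...` suffixes from the read names; when the stripped
#' names of a pair collide, `/1` and `/2` are appended to keep ids unique.
#'
#' @param path FASTQ file (read 1 of a pair, or single/interleaved reads).
#' @param path2 Optional FASTQ file holding the second mates.
#' @param offset Phred quality offset, 33 (default) or 64.
#' @return A list of [seq_record()] objects.
#' @export
read_fastq <- function(path, path2 = NULL, offset = 33L) {
  if (!file.exists(path)) stop("file not found: ", path)
  p1 <- parse_fastq_lines(readLines(path, warn = FALSE), path, offset)
  make_rec <- function(p, i, id) seq_record(id, p$seqs[i], p$quals[[i]])
  if (!is.null(path2)) {
    p2 <- parse_fastq_lines(readLines(path2, warn = FALSE), path2, offset)
    if (length(p1$ids) != length(p2$ids))
      stop("paired FASTQ files have different record counts")
    base1 <- strip_mate_suffix(p1$hdr)
    base2 <- strip_mate_suffix(p2$hdr)
    collide <- p1$ids == p2$ids
    id1 <- ifelse(collide, paste0(base1, "/1"), p1$ids)
    id2 <- ifelse(collide, paste0(base2, "/2"), p2$ids)
    recs <- vector("list", 2L * length(id1))
    for (i in seq_along(id1)) {
      r1 <- make_rec(p1, i, id1[i]); r1$mate_of <- id2[i]
      r2 <- make_rec(p2, i, id2[i]); r2$mate_of <- id1[i]
      recs[[2L * i - 1L]] <- r1
      recs[[2L * i]] <- r2
    }
  } else {
    recs <- lapply(seq_along(p1$ids), function(i)
      make_rec(p1, i, p1$ids[i]))
    # link interleaved mates: consecutive records with equal stripped names
    base <- strip_mate_suffix(p1$hdr)
    i <- 1L
    while (i < length(recs)) {
      if (base[i] == base[i + 1L] && recs[[i]]$id != recs[[i + 1L]]$id) {
        recs[[i]]$mate_of <- recs[[i + 1L]]$id
        recs[[i + 1L]]$mate_of <- recs[[i]]$id
        i <- i + 2L
      } else i <- i + 1L
    }
  }
  names(recs) <- vapply(recs, `[[`, character(1), "id")
  recs
}

#' Write records to a FASTA file
#'
#' @param records A list of [seq_record()] objects, a named character vector,
#'   or a list of contigs.
#' @param path Output path.
#' @param line_width Sequence line width (default 60).
#' @return `path`, invisibly. Round-trips through [read_fasta()] losslessly
#'   for ids and sequences.
#' @export
write_fasta <- function(records, path, line_width = 60L) {
  v <- as_named_seqs(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(v)) {
    writeLines(paste0(">", names(v)[i]), con)
    s <- v[[i]]
    n <- nchar(s)
    starts <- seq(1L, max(n, 1L), by = line_width)
    writeLines(substring(s, starts, pmin(starts + line_width - 1L, n)), con)
  }
  invisible(path)
}

# coerce records / contigs / named character to a named character vector
as_named_seqs <- function(records) {
  if (is.character(records)) {
    if (is.null(names(records)) && length(records))
      stop("character sequences must be named")
    return(records)
  }
  if (inherits(records, "seq_record") || inherits(records, "contig"))
    records <- list(records)
  ids <- vapply(records, function(r)
    if (is.list(r)) r$id else stop("cannot interpret records"), character(1))
  seqs <- vapply(records, `[[`, character(1), "sequence")
  setNames(seqs, ids)
}

#' Build an indexed read store
#'
#' The store plays the role of a searchable read database: ingestion order is
#' preserved, every id resolves to exactly one record, and retrieval by id
#' returns the ingested sequence.
#'
#' @param records List of [seq_record()] objects (or a named character vector
#'   of sequences). Duplicate ids are an error.
#' @return An object of class `read_store`.
#' @export
read_store <- function(records = list()) {
  store <- new.env(parent = emptyenv())
  store$index <- new.env(hash = TRUE, parent = emptyenv())
  store$ids <- character(0)
  store$nbases <- 0
  class(store) <- "read_store"
  if (length(records)) store_add(store, records)
  store
}

#' Add records to a read store
#' @param store A [read_store()].
#' @param records List of [seq_record()] or named character vector.
#' @return The store, invisibly (modified in place).
#' @export
store_add <- function(store, records) {
  if (is.character(records))
    records <- mapply(seq_record, names(records), records, SIMPLIFY = FALSE)
  for (r in records) {
    if (!inherits(r, "seq_record")) r <- do.call(seq_record, r)
    if (!is.null(store$index[[r$id]]))
      stop("duplicate read id '", r$id, "' in store")
    assign(r$id, r, envir = store$index)
    store$ids <- c(store$ids, r$id)
    store$nbases <- store$nbases + nchar(r$sequence)
  }
  invisible(store)
}

#' Retrieve records from a store by id
#' @param store A [read_store()].
#' @param ids Character vector of record ids.
#' @return A list of [seq_record()] in the order of `ids`.
#' @export
store_get <- function(store, ids) {
  lapply(ids, function(id) {
    r <- store$index[[id]]
    if (is.null(r)) stop("id '", id, "' not found in store")
    r
  })
}

#' @export
length.read_store <- function(x) length(x$ids)

#' Ids held in a store, in insertion order
#' @param store A [read_store()].
#' @return Character vector of ids.
#' @export
store_ids <- function(store) store$ids

#' Total number of stored bases
#'
#' Used as the database length in e-value computations.
#' @param store A [read_store()].
#' @return Numeric scalar.
#' @export
store_nbases <- function(store) store$nbases

#' @export
print.read_store <- function(x, ...) {
  cat("<read_store> ", length(x$ids), " records, ",
      format(x$nbases, big.mark = ","), " bases\n", sep = "")
  invisible(x)
}

#' Build a read store from sequence files
#'
#' @param paths FASTA or FASTQ files (FASTQ detected by a leading `@`).
#' @param offset Phred offset for FASTQ input.
#' @return A [read_store()].
#' @export
store_build <- function(paths, offset = 33L) {
  store <- read_store()
  for (p in paths) {
    first <- readLines(p, n = 1L)
    recs <- if (length(first) && startsWith(first, "@"))
      read_fastq(p, offset = offset) else read_fasta(p)
    store_add(store, recs)
  }
  store
}

#' Save / load a read store as FASTA plus a plain-text id index
#' @param store A [read_store()].
#' @param dir Directory to write (created if missing).
#' @return `dir` (save) or a [read_store()] (load).
#' @export
store_save <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- store_get(store, store$ids)
  write_fasta(recs, file.path(dir, "reads.fasta"))
  writeLines(store$ids, file.path(dir, "reads.ids"))
  invisible(dir)
}

#' @rdname store_save
#' @export
store_load <- function(dir) {
  store_build(file.path(dir, "reads.fasta"))
}

#' Reverse complement
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) revcomp_cpp(x)
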