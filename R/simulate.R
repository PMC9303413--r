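# Synthetic data: multi-allele locus generator, short paired-end and long
# read drawing, and the four-channel sequencing error model.

#' Sequencing error model
#'
#' Four error channels applied to a read: per-base substitution, single-base
#' deletion and single-base insertion, plus homopolymer run-length shifts
#' (+-1 base in a run of identical nucleotides). Presets:
#' `error_model_short()` = (0.005, 0.001, 0.001, 0.01), the Illumina-like
#' channel set with realized error somewhat below 0.01/base;
#' `error_model_long()` = (0.07, 0.01, 0.01, 0.80), the nanopore-like set
#' yielding roughly 90% alignment identity to the source.
#'
#' `runshift_unit` fixes what the run-shift probability applies to:
#' `"read"` (default) shifts one randomly chosen run of the read with
#' probability `p_runshift`; `"run"` applies it independently to every
#' maximal run of length >= `min_run`; `"run_base"` applies it per base
#' inside such runs. Only the per-read reading is compatible with a 0.80
#' probability and ~90% identity, because maximal runs of length >= 2 occur
#' at ~0.19/base in random sequence (see the methods vignette).
#'
#' @param p_sub,p_del,p_ins Per-base probabilities in `[0,1]`.
#' @param p_runshift Run-shift probability in `[0,1]`, interpreted per
#'   `runshift_unit`.
#' @param runshift_unit `"read"`, `"run"` or `"run_base"`.
#' @param min_run Minimum homopolymer run length eligible for a shift
#'   (default 2).
#' @return An object of class `error_model`.
#' @export
error_model <- function(p_sub = 0, p_del = 0, p_ins = 0, p_runshift = 0,
                        runshift_unit = c("read", "run", "run_base"),
                        min_run = 2L) {
  runshift_unit <- match.arg(runshift_unit)
  p <- c(p_sub, p_del, p_ins, p_runshift)
  stopifnot(all(p >= 0), all(p <= 1), min_run >= 2L)
  structure(list(p_sub = p_sub, p_del = p_del, p_ins = p_ins,
                 p_runshift = p_runshift, runshift_unit = runshift_unit,
                 min_run = as.integer(min_run)),
            class = "error_model")
}

#' @rdname error_model
#' @export
error_model_short <- function() error_model(0.005, 0.001, 0.001, 0.01)

#' @rdname error_model
#' @export
error_model_long <- function() error_model(0.07, 0.01, 0.01, 0.80)

#' Multi-allele locus model
#'
#' A random founder locus (default 7 kb) carries a relatively conserved
#' central core (default 1800 nt, centered) flanked by less conserved
#' sequence; alleles derive from the founder by independent per-site
#' substitution at the core and flank rates (defaults 0.005 and 0.02).
#'
#' @param founder_len Founder length (default 7000).
#' @param core_len Conserved core length (default 1800).
#' @param core_start 1-based core start; default centers the core.
#' @param p_mut_core,p_mut_flank Per-site substitution probabilities.
#' @param n_alleles Number of derived alleles (default 9).
#' @return An object of class `locus_model`.
#' @export
locus_model <- function(founder_len = 7000L, core_len = 1800L,
                        core_start = NULL, p_mut_core = 0.005,
                        p_mut_flank = 0.02, n_alleles = 9L) {
  if (is.null(core_start))
    core_start <- (founder_len - core_len) %/% 2L + 1L
  stopifnot(core_start >= 1L, core_start + core_len - 1L <= founder_len,
            p_mut_core >= 0, p_mut_core <= 1, p_mut_flank >= 0,
            p_mut_flank <= 1, n_alleles >= 1L)
  structure(list(founder_len = as.integer(founder_len),
                 core_len = as.integer(core_len),
                 core_start = as.integer(core_start),
                 p_mut_core = p_mut_core, p_mut_flank = p_mut_flank,
                 n_alleles = as.integer(n_alleles)),
            class = "locus_model")
}

#' Read profile
#'
#' @param kind `"paired_short"` (2 x `read_len` with a Normal insert),
#'   `"long"` (single reads, lengths uniform in `[long_min, long_max]`), or
#'   `"length_file"` (single reads with lengths drawn from `lengths`; when
#'   `lengths` is NULL a Uniform(300, 900) surrogate for medium-length
#'   pyrosequencing reads is used).
#' @param read_len Short-read length (default 150).
#' @param insert_mean,insert_sd Paired-end insert size distribution
#'   (defaults 400 and 50).
#' @param long_min,long_max Long-read length range (defaults 7000, 14000).
#' @param lengths Optional empirical length pool for `"length_file"`.
#' @return An object of class `read_profile`.
#' @export
read_profile <- function(kind = c("paired_short", "long", "length_file"),
                         read_len = 150L, insert_mean = 400L,
                         insert_sd = 50L, long_min = 7000L,
                         long_max = 14000L, lengths = NULL) {
  kind <- match.arg(kind)
  stopifnot(read_len >= 1L, long_min <= long_max)
  structure(list(kind = kind, read_len = as.integer(read_len),
                 insert_mean = as.integer(insert_mean),
                 insert_sd = as.integer(insert_sd),
                 long_min = as.integer(long_min),
                 long_max = as.integer(long_max), lengths = lengths),
            class = "read_profile")
}

#' Generate a random founder sequence
#'
#' @param model A [locus_model()].
#' @param base_freqs Nucleotide frequencies (named or in ACGT order);
#'   `"uniform"` or the AT-rich `"dirigent"` preset (A/T 0.3, C/G 0.2)
#'   typical of a wheat dirigent-like gene region.
#' @return A nucleotide string of length `model$founder_len`.
#' @export
make_founder <- function(model = locus_model(), base_freqs = "uniform") {
  if (is.character(base_freqs))
    base_freqs <- switch(match.arg(base_freqs, c("uniform", "dirigent")),
                         uniform = rep(0.25, 4),
                         dirigent = c(0.3, 0.2, 0.2, 0.3))
  stopifnot(length(base_freqs) == 4L, all(base_freqs >= 0),
            sum(base_freqs) > 0)
  paste(sample(c("A", "C", "G", "T"), model$founder_len, replace = TRUE,
               prob = base_freqs), collapse = "")
}

#' Derive mutated alleles from a founder
#'
#' Each allele substitutes every site independently (to a uniformly chosen
#' different base) with the core rate inside the conserved core and the
#' flank rate outside it.
#'
#' @param founder Founder string from [make_founder()].
#' @param model A [locus_model()].
#' @return Named character vector (`allele1..alleleN`) with attribute
#'   `"snps"`: a data frame (allele, pos, ref, alt) of the introduced
#'   substitutions.
#' @export
make_alleles <- function(founder, model = locus_model()) {
  L <- nchar(founder)
  stopifnot(L == model$founder_len)
  fch <- strsplit(founder, "", fixed = TRUE)[[1]]
  core <- seq(model$core_start, length.out = model$core_len)
  p <- rep(model$p_mut_flank, L)
  p[core] <- model$p_mut_core
  alleles <- character(model$n_alleles)
  snps <- list()
  bases <- c("A", "C", "G", "T")
  for (a in seq_len(model$n_alleles)) {
    hit <- which(runif(L) < p)
    ach <- fch
    if (length(hit)) {
      alt <- vapply(fch[hit], function(b)
        sample(setdiff(bases, b), 1L), character(1))
      ach[hit] <- alt
      snps[[a]] <- data.frame(allele = paste0("allele", a), pos = hit,
                              ref = fch[hit], alt = alt,
                              stringsAsFactors = FALSE)
    }
    alleles[a] <- paste(ach, collapse = "")
  }
  names(alleles) <- paste0("allele", seq_len(model$n_alleles))
  attr(alleles, "snps") <- if (length(snps)) do.call(rbind, snps) else
    data.frame(allele = character(0), pos = integer(0), ref = character(0),
               alt = character(0), stringsAsFactors = FALSE)
  alleles
}

#' Apply the error model to a read
#'
#' Positions are scanned left to right: substitution with `p_sub` (uniform
#' different base), deletion with `p_del`, insertion of a uniform base
#' before the position with `p_ins`. Independently, homopolymer runs shift
#' length by +-1 (equiprobable) according to `runshift_unit`. The events are
#' logged in attribute `"events"` as a data frame (type, pos) with `pos` on
#' the input read.
#'
#' @param read A [seq_record()] or character scalar.
#' @param em An [error_model()].
#' @return The mutated [seq_record()] with an `"events"` attribute.
#' @export
apply_errors <- function(read, em) {
  rec <- if (inherits(read, "seq_record")) read else
    seq_record(if (!is.null(names(read))) names(read)[1] else "read",
               as.character(read))
  ch <- strsplit(rec$sequence, "", fixed = TRUE)[[1]]
  n <- length(ch)
  bases <- c("A", "C", "G", "T")
  ev_type <- character(0); ev_pos <- integer(0)

  sub_i <- which(runif(n) < em$p_sub)
  if (length(sub_i)) {
    ch[sub_i] <- vapply(ch[sub_i], function(b)
      sample(setdiff(bases, b), 1L), character(1))
    ev_type <- c(ev_type, rep("sub", length(sub_i)))
    ev_pos <- c(ev_pos, sub_i)
  }
  del_i <- runif(n) < em$p_del
  ins_i <- runif(n) < em$p_ins
  if (any(del_i)) {
    ev_type <- c(ev_type, rep("del", sum(del_i)))
    ev_pos <- c(ev_pos, which(del_i))
  }
  if (any(ins_i)) {
    ev_type <- c(ev_type, rep("ins", sum(ins_i)))
    ev_pos <- c(ev_pos, which(ins_i))
  }
  # emit: optional inserted base before each position, base unless deleted
  pieces <- ch
  pieces[del_i] <- ""
  if (any(ins_i))
    pieces[ins_i] <- paste0(sample(bases, sum(ins_i), replace = TRUE),
                            pieces[ins_i])
  s <- paste(pieces, collapse = "")

  # homopolymer run-length shifts on the read as sequenced so far
  r <- rle(strsplit(s, "", fixed = TRUE)[[1]])
  eligible <- which(r$lengths >= em$min_run)
  shift_runs <- integer(0)
  if (length(eligible) && em$p_runshift > 0) {
    if (em$runshift_unit == "read") {
      if (runif(1) < em$p_runshift)
        shift_runs <- sample(eligible, 1L)
    } else if (em$runshift_unit == "run") {
      shift_runs <- eligible[runif(length(eligible)) < em$p_runshift]
    } else {
      pr <- 1 - (1 - em$p_runshift)^(r$lengths[eligible])
      shift_runs <- eligible[runif(length(eligible)) < pr]
    }
  }
  if (length(shift_runs)) {
    delta <- sample(c(-1L, 1L), length(shift_runs), replace = TRUE)
    runpos <- cumsum(r$lengths) - r$lengths + 1L
    r$lengths[shift_runs] <- pmax(r$lengths[shift_runs] + delta, 1L)
    s <- paste(inverse.rle(r), collapse = "")
    ev_type <- c(ev_type, rep("runshift", length(shift_runs)))
    ev_pos <- c(ev_pos, runpos[shift_runs])
  }
  out <- seq_record(rec$id, s)
  out$mate_of <- rec$mate_of
  attr(out, "events") <- data.frame(type = ev_type, pos = ev_pos,
                                    stringsAsFactors = FALSE)
  out
}

#' Draw simulated reads from one or more source sequences
#'
#' Start positions and strands are uniform; `paired_short` emits mates on
#' opposite strands separated by a Normal(`insert_mean`, `insert_sd`) insert
#' truncated to the template. Total drawn bases approximate `coverage` times
#' the total genome length. Read ids encode source, 1-based start and strand
#' (`<source>:<start>:<strand>:r<serial>[/1|/2]`) for truth tracking.
#'
#' @param genome Named character vector of source sequences (a single
#'   unnamed string is named `"ref"`).
#' @param profile A [read_profile()].
#' @param coverage Target fold-coverage (> 0).
#' @param em Optional [error_model()] applied to every read.
#' @return List of [seq_record()]; attribute `"truth"` is a data frame with
#'   one row per read (read_id, source, start, strand, length and error
#'   event counts).
#' @export
draw_reads <- function(genome, profile = read_profile("long"), coverage,
                       em = NULL) {
  stopifnot(coverage > 0)
  if (is.null(names(genome))) names(genome) <- paste0("ref",
                                                      seq_along(genome))
  glen <- nchar(genome)
  total <- sum(glen)
  target <- coverage * total
  recs <- list()
  truth <- list()
  serial <- 0L
  drawn <- 0
  src_p <- glen / total
  gch <- unname(genome)

  emit <- function(source, start, strand, seqstr, suffix = "") {
    serial <<- serial + 1L
    id <- paste0(source, ":", start, ":", strand, ":r", serial, suffix)
    rec <- seq_record(id, seqstr)
    nev <- c(sub = 0L, del = 0L, ins = 0L, runshift = 0L)
    if (!is.null(em)) {
      rec <- apply_errors(rec, em)
      ev <- attr(rec, "events")
      if (nrow(ev)) {
        tb <- table(ev$type)
        nev[names(tb)] <- as.integer(tb)
      }
    }
    recs[[length(recs) + 1L]] <<- rec
    truth[[length(truth) + 1L]] <<- data.frame(
      read_id = rec$id, source = source, start = start, strand = strand,
      src_len = nchar(seqstr), emitted_len = nchar(rec$sequence),
      n_sub = nev[["sub"]], n_del = nev[["del"]], n_ins = nev[["ins"]],
      n_runshift = nev[["runshift"]], stringsAsFactors = FALSE)
    drawn <<- drawn + nchar(seqstr)
  }

  while (drawn < target) {
    src <- if (length(genome) == 1L) 1L else
      sample.int(length(genome), 1L, prob = src_p)
    L <- glen[src]
    if (profile$kind == "paired_short") {
      rl <- profile$read_len
      ins <- round(rnorm(1, profile$insert_mean, profile$insert_sd))
      ins <- max(ins, 2L * rl)
      ins <- min(ins, L)
      if (L < 2L * rl) {
        warning("template shorter than a read pair; truncating")
        ins <- L
      }
      start <- sample.int(max(L - ins + 1L, 1L), 1L)
      tmpl_strand <- sample(c("+", "-"), 1L)
      s1 <- substr(gch[src], start, min(start + rl - 1L, L))
      s2r <- substr(gch[src], max(start + ins - rl, 1L), start + ins - 1L)
      s2 <- as.character(revcomp(s2r))
      start2 <- start + ins - nchar(s2r)
      if (tmpl_strand == "+") {
        emit(names(genome)[src], start, "+", s1, "/1")
        emit(names(genome)[src], start2, "-", s2, "/2")
      } else {
        emit(names(genome)[src], start2, "-", s2, "/1")
        emit(names(genome)[src], start, "+", s1, "/2")
      }
      k <- length(recs)
      recs[[k - 1L]]$mate_of <- recs[[k]]$id
      recs[[k]]$mate_of <- recs[[k - 1L]]$id
    } else {
      rl <- if (profile$kind == "long")
        sample(seq(profile$long_min, profile$long_max), 1L)
      else if (!is.null(profile$lengths)) {
        if (length(profile$lengths) == 1L) profile$lengths
        else sample(profile$lengths, 1L)
      } else sample(300:900, 1L)
      if (rl > L) {
        warning("read longer than template; truncated to template length")
        rl <- L
      }
      start <- sample.int(L - rl + 1L, 1L)
      strand <- sample(c("+", "-"), 1L)
      s <- substr(gch[src], start, start + rl - 1L)
      if (strand == "-") s <- as.character(revcomp(s))
      emit(names(genome)[src], start, strand, s)
    }
  }
  truth <- do.call(rbind, truth)
  names(recs) <- truth$read_id
  attr(recs, "truth") <- truth
  recs
}

#' Simulate the standard multi-allele locus with reads
#'
#' Convenience wrapper: founder, alleles, and reads drawn across all alleles.
#'
#' @param model A [locus_model()].
#' @param profile A [read_profile()].
#' @param coverage Fold-coverage over the pooled alleles.
#' @param em Optional [error_model()].
#' @param base_freqs Passed to [make_founder()].
#' @return List with `founder`, `alleles` (with SNP truth attribute) and
#'   `reads` (with truth attribute).
#' @export
simulate_locus_reads <- function(model = locus_model(),
                                 profile = read_profile("length_file"),
                                 coverage = 5, em = NULL,
                                 base_freqs = "uniform") {
  founder <- make_founder(model, base_freqs)
  alleles <- make_alleles(founder, model)
  reads <- draw_reads(alleles, profile, coverage, em)
  list(founder = founder, alleles = alleles, reads = reads)
}
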