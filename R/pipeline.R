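# The cycle engine: seed -> search -> select -> (fragment) -> assemble ->
# contig-select -> (polish) -> repeat, with stopping criteria and outputs.

#' Pipeline configuration
#'
#' @param seeds Seed sequences: path to a FASTA file, or a list of
#'   [seq_record()].
#' @param store Read set: a [read_store()], or path(s) to FASTA/FASTQ files.
#' @param seed_alphabet `"nucleotide"` or `"protein"`; protein seeds use
#'   translated search for read gathering at cycle 1 and for contig
#'   selection.
#' @param evalue_initial E-value cutoff for the cycle-1 seed-vs-reads search
#'   (default 1e-10).
#' @param evalue_cycle E-value cutoff for later-cycle searches and for
#'   contig selection (default 1e-20).
#' @param max_hits Maximum reads retrieved per search (default 10000).
#' @param selection A [selection_policy()] (default increment mode, 10 per
#'   cycle).
#' @param frag `"off"`, `"single"` or `"double"` long-read fragmentation of
#'   the selected reads.
#' @param frag_len,frag_len2 Fragment lengths (defaults 600; 490 for the
#'   second tiling under `"double"`).
#' @param include_mates Also pull in paired-end mates of selected reads
#'   (default FALSE).
#' @param assembler `"builtin"` or a tool spec list for
#'   [external_assembler()].
#' @param asm An [assembler_params()].
#' @param polish_iterations Polishing iterations per cycle (default 0 = off;
#'   5 is the customary maximum).
#' @param polish_min_depth Minimum pileup depth for polishing edits.
#' @param max_cycles Maximum number of cycles (default 21).
#' @param minprogress Stop when consecutive cycles' longest matching contigs
#'   differ in length by less than this (default 100; 0 disables).
#' @param outdir Output directory for per-cycle FASTA files, `report.tsv`
#'   and `run.log`; NULL keeps everything in memory.
#' @param seed Random seed governing all randomness in a run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seeds, store,
                            seed_alphabet = c("nucleotide", "protein"),
                            evalue_initial = 1e-10, evalue_cycle = 1e-20,
                            max_hits = 10000L,
                            selection = selection_policy(),
                            frag = c("off", "single", "double"),
                            frag_len = 600L, frag_len2 = 490L,
                            include_mates = FALSE,
                            assembler = "builtin",
                            asm = assembler_params(keep_singletons = TRUE),
                            polish_iterations = 0L, polish_min_depth = 2L,
                            max_cycles = 21L, minprogress = 100L,
                            outdir = NULL, seed = 1L) {
  seed_alphabet <- match.arg(seed_alphabet)
  frag <- match.arg(frag)
  stopifnot(evalue_initial > 0, evalue_cycle > 0, max_cycles >= 1L,
            minprogress >= 0L, polish_iterations >= 0L)
  structure(list(seeds = seeds, store = store,
                 seed_alphabet = seed_alphabet,
                 evalue_initial = evalue_initial,
                 evalue_cycle = evalue_cycle,
                 max_hits = as.integer(max_hits), selection = selection,
                 frag = frag, frag_len = as.integer(frag_len),
                 frag_len2 = as.integer(frag_len2),
                 include_mates = isTRUE(include_mates),
                 assembler = assembler, asm = asm,
                 polish_iterations = as.integer(polish_iterations),
                 polish_min_depth = as.integer(polish_min_depth),
                 max_cycles = as.integer(max_cycles),
                 minprogress = as.integer(minprogress), outdir = outdir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized keys mirror [pipeline_config()]; selection is given through
#' `mode`, `bitscore_min`, `extincrement` and `manual_counts`, assembly
#' through `min_overlap`, `min_identity`, `keep_singletons`.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  sel <- selection_policy(
    mode = y$mode %||% "increment",
    bitscore_min = y$bitscore_min %||% NA_real_,
    increment = y$extincrement %||% 10L,
    manual_counts = y$manual_counts %||% integer(0))
  asm <- assembler_params(
    min_overlap = y$min_overlap %||% 40L,
    min_identity = y$min_identity %||% 0.83,
    keep_singletons = y$keep_singletons %||% TRUE)
  args <- y[names(y) %in% names(formals(pipeline_config))]
  args$selection <- sel
  args$asm <- asm
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_report <- function() {
  data.frame(cycle = integer(0), n_reads_selected = integer(0),
             n_contigs_all = integer(0), n_contigs_matching = integer(0),
             longest_all = integer(0), longest_matching = integer(0),
             mean_len_all = numeric(0), mean_len_matching = numeric(0),
             stop_reason = character(0), stringsAsFactors = FALSE)
}

cycle_report <- function(cycle, n_sel, all_len, match_len,
                         stop_reason = NA_character_) {
  data.frame(cycle = cycle, n_reads_selected = n_sel,
             n_contigs_all = length(all_len),
             n_contigs_matching = length(match_len),
             longest_all = if (length(all_len)) max(all_len) else 0L,
             longest_matching = if (length(match_len)) max(match_len)
                                else 0L,
             mean_len_all = if (length(all_len)) mean(all_len) else 0,
             mean_len_matching = if (length(match_len)) mean(match_len)
                                 else 0,
             stop_reason = stop_reason, stringsAsFactors = FALSE)
}

resolve_store <- function(store) {
  if (inherits(store, "read_store")) store else store_build(store)
}

resolve_seeds <- function(seeds, alphabet) {
  if (is.character(seeds) && length(seeds) == 1L && file.exists(seeds))
    read_fasta(seeds, alphabet = alphabet)
  else if (is.character(seeds)) as.list(as_named_seqs(seeds))
  else seeds
}

#' Run one retrieval-assembly cycle
#'
#' Cycle 1 queries the store with the seed sequences (translated search for
#' protein seeds) at `evalue_initial`; later cycles query with the surviving
#' contigs at `evalue_cycle`. Selected reads (optionally fragmented) are
#' assembled; contigs matching the ORIGINAL seeds at `evalue_cycle` survive
#' and are polished when configured. Only the matching contigs pass to the
#' next cycle.
#'
#' @param state List with `cycle` (>= 1), `queries` (seed records at cycle
#'   1, contigs afterwards), `previous_ids`, and internal bookkeeping; pass
#'   the value returned by the previous call (or `NULL` to start).
#' @param config A [pipeline_config()].
#' @return Updated state; fields `contigs` (matching, possibly polished),
#'   `contigs_all`, `report` (the cycle's [cycle_report] row) and `log`.
#' @export
run_cycle <- function(state, config) {
  if (is.null(state)) {
    store <- resolve_store(config$store)
    if (length(store) == 0L) stop("read store is empty")
    seeds <- resolve_seeds(config$seeds, config$seed_alphabet)
    state <- list(cycle = 1L, queries = seeds, previous_ids = character(0),
                  store = store, seeds = seeds, reports = empty_report(),
                  log = character(0), contigs = list())
  }
  cyc <- state$cycle
  seed_scheme <- scoring_scheme(config$seed_alphabet)
  nuc_scheme <- scoring_scheme("nucleotide")
  first <- cyc == 1L
  scheme <- if (first) seed_scheme else nuc_scheme
  cutoff <- if (first) config$evalue_initial else config$evalue_cycle
  queries <- if (first) state$queries else
    lapply(state$queries, function(ct)
      seq_record(paste0("cyc", cyc - 1L, "_", ct$id), ct$sequence))

  state$log <- c(state$log, sprintf(
    "cycle %d: search %d queries vs %d reads (evalue<=%g, max_hits=%d, %s)",
    cyc, length(queries), length(state$store), cutoff, config$max_hits,
    scheme$type))
  hits <- search_store(queries, state$store, evalue_cutoff = cutoff,
                       max_hits = config$max_hits, scheme = scheme)
  ranked <- attr(hits, "ranked")
  if (nrow(ranked) == 0L) {
    state$report <- cycle_report(cyc, 0L, integer(0), integer(0),
                                 "no_matching_reads")
    state$reports <- rbind(state$reports, state$report)
    state$contigs <- list()
    return(state)
  }

  sel <- tryCatch(
    select_reads(ranked, config$selection, cyc, state$previous_ids),
    manual_exhausted = function(e) e)
  if (inherits(sel, "condition")) {
    state$report <- cycle_report(cyc, 0L, integer(0), integer(0),
                                 "manual_exhausted")
    state$reports <- rbind(state$reports, state$report)
    state$contigs <- list()
    return(state)
  }
  state$log <- c(state$log, sprintf(
    "cycle %d: selected %d of %d ranked reads (%s mode)", cyc,
    length(sel), nrow(ranked), config$selection$mode))

  recs <- store_get(state$store, sel)
  if (config$include_mates) {
    mates <- unlist(lapply(recs, `[[`, "mate_of"))
    mates <- setdiff(mates[!is.na(mates)], sel)
    mates <- intersect(mates, store_ids(state$store))
    if (length(mates)) recs <- c(recs, store_get(state$store, mates))
  }
  recs <- apply_fragmentation(recs, config$frag, config$frag_len,
                              config$frag_len2)

  state$log <- c(state$log, sprintf(
    "cycle %d: assembling %d sequences (%s; min_overlap=%d, min_identity=%g)",
    cyc, length(recs), if (identical(config$assembler, "builtin"))
      "builtin greedy" else "external", config$asm$min_overlap,
    config$asm$min_identity))
  contigs_all <- if (identical(config$assembler, "builtin"))
    greedy_assemble(recs, config$asm)
  else external_assembler(recs, config$assembler)

  all_len <- vapply(contigs_all, function(ct) nchar(ct$sequence), integer(1))

  # contig selection: original seeds vs the new contigs
  matching <- list()
  if (length(contigs_all)) {
    cseqs <- setNames(vapply(contigs_all, `[[`, character(1), "sequence"),
                      vapply(contigs_all, `[[`, character(1), "id"))
    hit_ids <- character(0)
    for (sd in state$seeds) {
      h <- align_local(sd, cseqs, scheme = seed_scheme)
      h <- h[h$evalue <= config$evalue_cycle, , drop = FALSE]
      hit_ids <- union(hit_ids, h$subject_id)
    }
    matching <- contigs_all[vapply(contigs_all, `[[`, character(1), "id")
                            %in% hit_ids]
    state$log <- c(state$log, sprintf(
      "cycle %d: %d of %d contigs match the seeds at evalue<=%g", cyc,
      length(matching), length(contigs_all), config$evalue_cycle))
  }
  match_len <- vapply(matching, function(ct) nchar(ct$sequence), integer(1))

  polished <- matching
  if (config$polish_iterations > 0L && length(matching)) {
    polished <- lapply(matching, function(ct)
      polish(ct, state$store, iterations = config$polish_iterations,
             min_depth = config$polish_min_depth))
    state$log <- c(state$log, sprintf(
      "cycle %d: polished %d contigs (%d iterations, min_depth=%d)", cyc,
      length(polished), config$polish_iterations, config$polish_min_depth))
  }

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    if (length(matching))
      write_fasta(matching, file.path(config$outdir,
                                      sprintf("cycle_%d.fasta", cyc)))
    if (config$polish_iterations > 0L && length(polished))
      write_fasta(polished, file.path(
        config$outdir, sprintf("cycle_%d.polished.fasta", cyc)))
  }

  state$report <- cycle_report(cyc, length(sel), all_len, match_len)
  state$reports <- rbind(state$reports, state$report)
  state$contigs <- polished
  state$contigs_all <- contigs_all
  state$previous_ids <- sel
  state$queries <- polished
  state$cycle <- cyc + 1L
  state
}

#' Decide whether the run should stop
#'
#' Reasons, in the order tested: `no_matching_reads` / `manual_exhausted`
#' (recorded by the cycle itself), `no_contigs`, `no_matching_contigs`,
#' `minprogress_stalled` (consecutive cycles' longest matching contigs
#' differ by less than `minprogress`; 0 disables), `max_cycles_reached`.
#'
#' @param reports Data frame of cycle reports (>= 1 row).
#' @param config A [pipeline_config()].
#' @return A stop reason string, or `NULL` to continue.
#' @export
should_stop <- function(reports, config) {
  stopifnot(nrow(reports) >= 1L)
  last <- reports[nrow(reports), ]
  if (!is.na(last$stop_reason)) return(last$stop_reason)
  if (last$n_contigs_all == 0L) return("no_contigs")
  if (last$n_contigs_matching == 0L) return("no_matching_contigs")
  if (config$minprogress > 0L && nrow(reports) >= 2L) {
    prev <- reports[nrow(reports) - 1L, ]
    if (abs(last$longest_matching - prev$longest_matching) <
        config$minprogress)
      return("minprogress_stalled")
  }
  if (last$cycle >= config$max_cycles) return("max_cycles_reached")
  NULL
}

#' Run the full seeded local assembly pipeline
#'
#' Iterates [run_cycle()] until [should_stop()] fires. With an `outdir`,
#' writes `cycle_<N>.fasta` (matching contigs), `cycle_<N>.polished.fasta`
#' when polishing, `report.tsv` and `run.log` (every search/assembly/polish
#' call with its parameters). Fully deterministic given `config$seed`.
#'
#' @param config A [pipeline_config()].
#' @return The cycle-report data frame, with the final row's `stop_reason`
#'   filled in and the last surviving contigs as attribute `"contigs"`.
#' @export
run_pipeline <- function(config) {
  set.seed(config$seed)
  state <- NULL
  reason <- NULL
  repeat {
    state <- run_cycle(state, config)
    reason <- should_stop(state$reports, config)
    if (!is.null(reason)) break
  }
  reports <- state$reports
  reports$stop_reason[nrow(reports)] <- reason
  state$log <- c(state$log, paste0("stopped: ", reason))
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write.table(reports, file.path(config$outdir, "report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(state$log, file.path(config$outdir, "run.log"))
  }
  attr(reports, "contigs") <- state$contigs
  attr(reports, "log") <- state$log
  reports
}
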