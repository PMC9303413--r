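# Turning ranked hits into the read set assembled each cycle: the five
# selection modes and single/double long-read fragmentation.

#' Read-selection policy
#'
#' Five ways to limit the reads assembled in a cycle: `all` (every retrieved
#' read), `bitscore` (reads scoring at least `bitscore_min`), `increment`
#' (top `increment * cycle` reads), `population` (shortest ranked prefix,
#' extended whole bitscore-tie groups at a time, containing every read from
#' the previous cycle), and `manual` (top `manual_counts[cycle]` reads).
#'
#' @param mode One of `"all"`, `"bitscore"`, `"increment"`, `"population"`,
#'   `"manual"`.
#' @param bitscore_min Bitscore threshold for `bitscore` mode.
#' @param increment Per-cycle increment (>= 1) for `increment` mode;
#'   default 10.
#' @param manual_counts Integer vector of per-cycle read counts for `manual`
#'   mode.
#' @return An object of class `selection_policy`.
#' @export
selection_policy <- function(mode = c("increment", "all", "bitscore",
                                      "population", "manual"),
                             bitscore_min = NA_real_, increment = 10L,
                             manual_counts = integer(0)) {
  mode <- match.arg(mode)
  increment <- as.integer(increment)
  manual_counts <- as.integer(manual_counts)
  if (mode == "increment" && increment < 1L) stop("increment must be >= 1")
  if (mode == "bitscore" && !is.finite(bitscore_min))
    stop("bitscore mode needs a finite bitscore_min")
  if (mode == "manual" && (length(manual_counts) == 0L ||
                           any(manual_counts < 0L)))
    stop("manual mode needs non-negative manual_counts")
  structure(list(mode = mode, bitscore_min = bitscore_min,
                 increment = increment, manual_counts = manual_counts),
            class = "selection_policy")
}

manual_exhausted_condition <- function(cycle) {
  structure(class = c("manual_exhausted", "error", "condition"),
            list(message = paste0("manual read counts exhausted at cycle ",
                                  cycle),
                 call = sys.call(-1)))
}

#' Select reads for assembly from a ranked list
#'
#' @param ranked Data frame with columns `read_id` and `bitscore`, sorted by
#'   decreasing bitscore with ties broken by id (as from [rank_reads()]).
#' @param policy A [selection_policy()].
#' @param cycle Cycle number (>= 1).
#' @param previous_ids Ids selected in the previous cycle (used by
#'   `population` mode; previous ids no longer ranked are ignored with a
#'   warning).
#' @return Character vector of selected read ids, in rank order. In `manual`
#'   mode, a cycle beyond `length(manual_counts)` signals a condition of
#'   class `manual_exhausted` (a stopping criterion).
#' @export
select_reads <- function(ranked, policy, cycle = 1L,
                         previous_ids = character(0)) {
  stopifnot(inherits(policy, "selection_policy"), cycle >= 1L)
  ids <- ranked$read_id
  switch(policy$mode,
    all = ids,
    bitscore = ids[ranked$bitscore >= policy$bitscore_min],
    increment = head(ids, policy$increment * cycle),
    manual = {
      if (cycle > length(policy$manual_counts))
        stop(manual_exhausted_condition(cycle))
      head(ids, policy$manual_counts[cycle])
    },
    population = {
      missing <- setdiff(previous_ids, ids)
      if (length(missing)) {
        warning(length(missing),
                " previous-cycle read(s) no longer ranked; ignoring")
        previous_ids <- setdiff(previous_ids, missing)
      }
      if (length(previous_ids) == 0L) return(ids)
      # advance one bitscore-tie group at a time
      grp <- cumsum(!duplicated(ranked$bitscore))
      need <- max(grp[ids %in% previous_ids])
      ids[grp <= need]
    })
}

#' Break a read into non-overlapping fragments of one length
#'
#' Consecutive pieces of length `L`; the terminal remainder is kept as a
#' shorter fragment, so the concatenation of the fragments reconstructs the
#' read exactly.
#'
#' @param read A [seq_record()] (or named character scalar).
#' @param L Fragment length (>= 1).
#' @param scheme Fragment scheme tag used in ids (`"single"`, `"lenA"`,
#'   `"lenB"`).
#' @return List of fragments; each is a `seq_record` carrying `parent_id`,
#'   `offset` (0-based start on the parent) and `scheme` fields, with id
#'   `"<parent>_<scheme>_<ordinal>"`.
#' @export
fragment_single <- function(read, L, scheme = "single") {
  stopifnot(L >= 1L)
  if (is.character(read)) read <- seq_record(names(read)[1], read[[1]])
  n <- nchar(read$sequence)
  starts <- as.integer(seq(1L, n, by = L))
  lapply(seq_along(starts), function(i) {
    s <- substr(read$sequence, starts[i], min(starts[i] + L - 1L, n))
    f <- seq_record(paste(read$id, scheme, i, sep = "_"), s)
    f$parent_id <- read$id
    f$offset <- starts[i] - 1L
    f$scheme <- scheme
    class(f) <- c("fragment", class(f))
    f
  })
}

#' Break a read into fragments of two lengths
#'
#' The read is tiled twice, once at each length, and both tilings are pooled:
#' total fragment bases equal twice the read length, doubling the apparent
#' depth seen by an overlap assembler without adding new information.
#'
#' @param read A [seq_record()].
#' @param L1,L2 The two fragment lengths (defaults 610 and 490; must differ).
#' @return List of fragments with scheme tags `lenA` and `lenB`.
#' @export
fragment_double <- function(read, L1 = 610L, L2 = 490L) {
  stopifnot(L1 >= 1L, L2 >= 1L, L1 != L2)
  c(fragment_single(read, L1, scheme = "lenA"),
    fragment_single(read, L2, scheme = "lenB"))
}

# apply the configured fragmentation to a list of records
apply_fragmentation <- function(records, frag = c("off", "single", "double"),
                                frag_len = 600L, frag_len2 = 490L) {
  frag <- match.arg(frag)
  if (frag == "off") return(records)
  out <- list()
  for (r in records) {
    fr <- if (frag == "single") fragment_single(r, frag_len)
          else fragment_double(r, frag_len, frag_len2)
    out <- c(out, fr)
  }
  out
}
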