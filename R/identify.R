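STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Scan all six reading frames for ATG-initiated ORFs
#'
#' For each frame (+1, +2, +3 on the input strand; -1, -2, -3 on the
#' reverse complement) every ATG start codon opens one ORF running to the
#' first in-frame stop codon. ORFs that run off the sequence end without a
#' stop are reported with `complete = FALSE`. Codons containing `N` match
#' neither ATG nor a stop. Coordinates are 0-based half-open on the
#' scanned strand (i.e. on the reverse complement for minus frames); for
#' complete ORFs the interval includes the stop codon.
#'
#' @param seq A single nucleotide sequence (length >= 3).
#' @return `data.frame` with columns `frame` (one of `+1,+2,+3,-1,-2,-3`),
#'   `start`, `end`, `aa_length` (codons from ATG to the last codon before
#'   the stop, inclusive of the Met), `complete`.
#' @examples
#' scan_orfs("ATGAAATAA")  # one complete ORF, frame +1, 2 aa
#' @export
scan_orfs <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) < 3L) stop("sequence shorter than 3 nt")
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    n <- nchar(s)
    for (off in 0:2) {
      n_codons <- (n - off) %/% 3L
      if (n_codons < 1L) next
      pos <- off + 1L + 3L * (seq_len(n_codons) - 1L)
      codons <- substring(s, pos, pos + 2L)
      starts <- which(codons == "ATG")
      if (length(starts) == 0L) next
      stops <- which(codons %in% STOP_CODONS)
      # index of first stop at or after each start (starts are sorted)
      nxt <- findInterval(starts - 1L, stops) + 1L
      has_stop <- nxt <= length(stops)
      stop_idx <- ifelse(has_stop, stops[pmin(nxt, length(stops))], NA)
      aa <- ifelse(has_stop, stop_idx - starts, n_codons - starts + 1L)
      keep <- aa >= 1L
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        frame = paste0(strand, off + 1L),
        start = off + 3L * (starts[keep] - 1L),
        end = off + 3L * (starts[keep] - 1L) +
          3L * (aa[keep] + as.integer(has_stop[keep])),
        aa_length = as.integer(aa[keep]),
        complete = has_stop[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(frame = character(0), start = integer(0),
                      end = integer(0), aa_length = integer(0),
                      complete = logical(0)))
  }
  do.call(rbind, out)
}

#' Longest ORF length (amino acids) across six frames
#'
#' @param seq Nucleotide sequence.
#' @param require_complete If `TRUE`, only stop-terminated ORFs count.
#' @return Integer; 0 when no ORF exists.
#' @export
max_orf_aa <- function(seq, require_complete = FALSE) {
  orfs <- scan_orfs(seq)
  if (require_complete) orfs <- orfs[orfs$complete, , drop = FALSE]
  if (nrow(orfs) == 0L) return(0L)
  max(orfs$aa_length)
}

partition <- function(records, keep) {
  list(kept = records[keep, , drop = FALSE],
       removed = records[!keep, , drop = FALSE])
}

#' Length filter for lncRNA candidates
#'
#' Implements the "more than 200 nucleotides" rule strictly: with the
#' default `min_len = 201`, a 200-nt transcript is removed and a 201-nt
#' transcript kept.
#'
#' @param records A `seq_set`.
#' @param min_len Minimum retained length in nt (kept iff
#'   `length >= min_len`).
#' @return List with `kept` and `removed` sequence sets.
#' @export
filter_by_length <- function(records, min_len = 201L) {
  stopifnot(min_len >= 1L)
  partition(records, records$length >= min_len)
}

#' Six-frame ORF filter
#'
#' Removes transcripts whose longest ORF in any of the six frames exceeds
#' `max_aa` amino acids (default 100, i.e. "greater than 100 aa
#' eliminated"; a 100-aa ORF is kept, a 101-aa ORF removed). By default
#' ORFs truncated by the transcript end count toward the exclusion —
#' assembled fragments may lack stop codons, so this is the conservative
#' choice; set `require_complete = TRUE` to count only stop-terminated
#' ORFs.
#'
#' @inheritParams filter_by_length
#' @param max_aa Maximum tolerated ORF length in amino acids.
#' @param require_complete Count only complete (stop-terminated) ORFs.
#' @return List with `kept` and `removed` sequence sets.
#' @export
filter_by_orf <- function(records, max_aa = 100L, require_complete = FALSE) {
  stopifnot(max_aa >= 1L)
  mx <- vapply(records$seq, max_orf_aa, integer(1),
               require_complete = require_complete, USE.NAMES = FALSE)
  partition(records, mx <= max_aa)
}

#' Coding-potential score filter (ingested)
#'
#' Keeps transcripts with a coding-potential score strictly below
#' `keep_below` (default 0: "only the transcripts with scores less than 0
#' were used"). Transcripts absent from the table are kept with a warning
#' — the funnel removes candidates only on positive evidence of coding
#' capacity.
#'
#' @inheritParams filter_by_length
#' @param score_table Named numeric vector (see [read_score_table()]).
#' @param keep_below Retention cutoff (strict `<`).
#' @return List with `kept` and `removed` sequence sets.
#' @export
apply_score_filter <- function(records, score_table, keep_below = 0) {
  if (anyNA(score_table)) stop("malformed score in score table")
  sc <- score_table[records$id]
  missing <- is.na(sc)
  if (any(missing)) {
    warning(sum(missing), " transcripts missing from the score table ",
            "were kept")
  }
  partition(records, missing | sc < keep_below)
}

#' Protein-homology filter (ingested)
#'
#' Removes any transcript that appears as the query of at least one
#' protein-homology hit; transcripts with no hits are considered
#' non-coding candidates.
#'
#' @inheritParams filter_by_length
#' @param hit_table A hit table as returned by [read_blast_tab()].
#' @return List with `kept` and `removed` sequence sets.
#' @export
apply_homology_filter <- function(records, hit_table) {
  partition(records, !records$id %in% hit_table$query_id)
}

#' Run the lncRNA identification funnel
#'
#' Applies, in order: length filter, six-frame ORF filter, and (when the
#' corresponding tables are supplied) the coding-potential score filter
#' and the protein-homology filter. The stage report telescopes: each
#' stage's retained count is the next stage's input count and the final
#' retained count is the candidate lncRNA count.
#'
#' @inheritParams filter_by_length
#' @param score_table Optional named numeric score vector.
#' @param hit_table Optional protein-homology hit table.
#' @inheritParams filter_by_orf
#' @return List with `candidates` (a `seq_set`) and `report` (data.frame
#'   with columns `stage`, `input`, `removed`, `retained`).
#' @export
run_identification <- function(records, min_len = 201L, max_aa = 100L,
                               score_table = NULL, hit_table = NULL,
                               require_complete = FALSE) {
  stages <- list(
    length = function(r) filter_by_length(r, min_len),
    orf = function(r) filter_by_orf(r, max_aa, require_complete))
  if (!is.null(score_table)) {
    stages$coding_score <- function(r) apply_score_filter(r, score_table)
  }
  if (!is.null(hit_table)) {
    stages$homology <- function(r) apply_homology_filter(r, hit_table)
  }
  cur <- records
  report <- data.frame(stage = character(0), input = integer(0),
                       removed = integer(0), retained = integer(0))
  for (nm in names(stages)) {
    res <- stages[[nm]](cur)
    report <- rbind(report, data.frame(
      stage = nm, input = nrow(cur), removed = nrow(res$removed),
      retained = nrow(res$kept)))
    cur <- res$kept
  }
  list(candidates = cur, report = report)
}
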