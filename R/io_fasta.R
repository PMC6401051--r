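#' Read a nucleotide FASTA file
#'
#' Parses a (possibly multi-line) FASTA file into a sequence set. The record
#' id is the first whitespace-delimited token of the header; the full header
#' is retained as the description. `U` is normalized to `T` so that miRNA
#' (RNA) and transcript (DNA) alphabets unify; sequences are stored upper
#' case. Only the IUPAC subset `A`, `C`, `G`, `T`, `N` is accepted.
#'
#' @param path Path to a FASTA file. May be empty (zero records).
#' @return A `data.frame` of class `seq_set` with columns `id`,
#'   `description`, `seq` and `length`, one row per record, in file order.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">t1 demo", "ACGT", "ACGT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_seq_set())
  if (!startsWith(lines[[1L]], ">")) {
    stop("not a FASTA file (does not begin with '>'): ", path)
  }
  hdr <- startsWith(lines, ">")
  rec_idx <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][[1L]])
  }
  body <- !hdr
  seqs <- vapply(split(lines[body], rec_idx[body]), paste0,
                 character(1), collapse = "")
  out <- rep("", length(ids))
  out[as.integer(names(seqs))] <- seqs
  out <- toupper(chartr("u", "t", chartr("U", "T", out)))
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) {
    # report the first offending input line for diagnosis
    line_no <- which(body & grepl("[^ACGTNacgtnUu]", lines))[1]
    stop("non-IUPAC nucleotide character in record '", ids[bad][[1L]],
         "' (file line ", line_no, ")")
  }
  if (any(!nzchar(out))) {
    stop("FASTA record with empty sequence: ", ids[!nzchar(out)][[1L]])
  }
  seq_set(ids, headers, out)
}

#' Construct a sequence set
#'
#' The in-memory carrier for FASTA content: a data.frame with one row per
#' record and columns `id`, `description`, `seq`, `length`.
#'
#' @param id Character vector of record ids.
#' @param description Full headers (defaults to the ids).
#' @param seq Upper-case nucleotide sequences.
#' @return A `seq_set` data.frame.
#' @export
seq_set <- function(id, description = id, seq) {
  out <- data.frame(id = id, description = description, seq = seq,
                    length = nchar(seq), stringsAsFactors = FALSE)
  class(out) <- c("seq_set", "data.frame")
  out
}

empty_seq_set <- function() {
  seq_set(character(0), character(0), character(0))
}

#' Write a sequence set to FASTA
#'
#' Sequences are wrapped at 60 characters per line. Round-trips with
#' [read_fasta()] on id and sequence content.
#'
#' @param records A `seq_set` (or data.frame with `id`, `seq`, and
#'   optionally `description` columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description
          else records$id
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", desc[[i]]), con)
    s <- records$seq[[i]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement of DNA sequences
#'
#' @param seq Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  comp <- chartr("ACGTN", "TGCAN", toupper(seq))
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
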