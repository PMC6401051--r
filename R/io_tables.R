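#' Read BLAST tabular (outfmt 6) hits
#'
#' Strict reader for the 12-column tab-separated BLAST output dialect.
#' Lines starting with `#` are skipped. A subject interval with
#' `s_start > s_end` encodes a minus-strand subject orientation; the reader
#' records this in a derived `s_strand` column and leaves the raw
#' coordinates untouched.
#'
#' @param path Path to a tabular hit file.
#' @return `data.frame` with the 12 standard columns (`query_id`,
#'   `subject_id`, `percent_identity`, `align_length`, `mismatches`,
#'   `gap_opens`, `q_start`, `q_end`, `s_start`, `s_end`, `evalue`,
#'   `bit_score`) plus `s_strand` (`"+"`/`"-"`).
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  cols <- c("query_id", "subject_id", "percent_identity", "align_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start",
            "s_end", "evalue", "bit_score")
  if (length(lines) == 0L) {
    out <- data.frame(matrix(nrow = 0, ncol = 12,
                             dimnames = list(NULL, cols)))
    out$query_id <- character(0); out$subject_id <- character(0)
    out$s_strand <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[[1L]]
    stop("hit table line ", lineno[[bad]], ": expected 12 columns, found ",
         nf[[bad]])
  }
  m <- do.call(rbind, fields)
  out <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                    stringsAsFactors = FALSE)
  num <- apply(m[, 3:12, drop = FALSE], 2L, as.numeric)
  num <- matrix(num, ncol = 10)
  colnames(num) <- cols[3:12]
  if (anyNA(num)) stop("hit table: non-numeric value in a numeric column")
  out <- cbind(out, as.data.frame(num))
  if (any(out$q_start > out$q_end)) {
    stop("hit table: q_start > q_end (query coordinates must be forward)")
  }
  out$s_strand <- ifelse(out$s_start <= out$s_end, "+", "-")
  out
}

#' Read an expression matrix with sample metadata
#'
#' The expression TSV has a header row; the first column is the transcript
#' id and the remaining columns are samples (FPKM). The sample sheet TSV
#' has columns `sample`, `tissue`, `stage`, `replicate` and must cover
#' every expression column exactly once.
#'
#' @param expr_path Expression TSV path.
#' @param samples_path Sample sheet TSV path.
#' @return List with `fpkm` (numeric matrix, transcripts x samples) and
#'   `samples` (data.frame with a derived `condition = tissue.stage`
#'   column).
#' @export
read_expression <- function(expr_path, samples_path) {
  tab <- read.delim(expr_path, check.names = FALSE,
                    stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(mat) <- tab[[1L]]
  storage.mode(mat) <- "numeric"
  if (anyNA(mat)) stop("expression matrix contains non-numeric values")
  if (any(mat < 0)) stop("expression matrix contains negative FPKM values")
  samples <- read.delim(samples_path, stringsAsFactors = FALSE)
  need <- c("sample", "tissue", "stage", "replicate")
  if (!all(need %in% names(samples))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  if (!setequal(samples$sample, colnames(mat)) ||
      anyDuplicated(samples$sample)) {
    stop("sample sheet does not match expression matrix columns")
  }
  samples <- samples[match(colnames(mat), samples$sample), ]
  samples$condition <- paste(samples$tissue, samples$stage, sep = ".")
  list(fpkm = mat, samples = samples)
}

#' Read a transcript -> annotation-term table
#'
#' Two- or three-column TSV with header (`transcript_id`, `term`, and
#' optionally `label`). Term accessions must look like `PREFIX:digits`
#' (e.g. `GO:0015979`). Duplicate (transcript, term) pairs are collapsed
#' with a warning.
#'
#' @param path TSV path.
#' @return `data.frame` with columns `transcript_id`, `term`, `label`.
#' @export
read_term_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "term") %in% names(tab))) {
    stop("term table must have columns transcript_id and term")
  }
  bad <- !grepl("^[A-Za-z]+:[0-9]+$", tab$term)
  if (any(bad)) {
    stop("malformed term accession: ", tab$term[bad][[1L]])
  }
  if (!"label" %in% names(tab)) tab$label <- ""
  dup <- duplicated(tab[c("transcript_id", "term")])
  if (any(dup)) {
    warning(sum(dup), " duplicate (transcript, term) pairs collapsed")
    tab <- tab[!dup, ]
  }
  tab[c("transcript_id", "term", "label")]
}

#' Read a coding-potential score table
#'
#' TSV with header columns `transcript_id` and `score` (the ingested
#' output of an external coding-potential tool; negative means
#' non-coding).
#'
#' @param path TSV path.
#' @return Named numeric vector of scores keyed by transcript id.
#' @export
read_score_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "score") %in% names(tab))) {
    stop("score table must have columns transcript_id and score")
  }
  sc <- suppressWarnings(as.numeric(tab$score))
  if (anyNA(sc)) {
    stop("malformed coding-potential score for transcript ",
         tab$transcript_id[is.na(sc)][[1L]])
  }
  setNames(sc, tab$transcript_id)
}

#' Read a plain-text id list (one id per line)
#'
#' @param path File path.
#' @return Character vector of ids.
#' @export
read_id_list <- function(path) {
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids)
  ids[nzchar(ids)]
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
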