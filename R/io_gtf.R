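#' Transcript model constructor
#'
#' A transcript model is a stranded chain of exons on one chromosome. Exon
#' coordinates are 0-based half-open (the package-internal convention;
#' conversion to/from the 1-based inclusive GTF convention happens only at
#' file boundaries). Introns are derived as the gaps between consecutive
#' exons, never stored.
#'
#' @param id Transcript id.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (`start`, `end`), 0-based half-open.
#' @param gene_id Optional gene id.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(id, chrom, strand, exons, gene_id = id) {
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L])) {
    stop("transcript ", id, ": exon with non-positive length")
  }
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] < exons[-nrow(exons), 2L])) {
    stop("transcript ", id, ": overlapping exons")
  }
  if (!strand %in% c("+", "-")) {
    stop("transcript ", id, ": strand must be '+' or '-'")
  }
  structure(list(id = id, chrom = chrom, strand = strand,
                 exons = exons, gene_id = gene_id),
            class = "transcript_model")
}

#' Introns of a transcript model
#'
#' @param model A `transcript_model`.
#' @return Two-column matrix of 0-based half-open intron intervals (zero
#'   rows for single-exon models).
#' @export
model_introns <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  if (n < 2L) {
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = ex[-n, 2L], end = ex[-1L, 1L])
}

#' Read transcript models from a GTF file
#'
#' Only `exon` features are used; each must carry `transcript_id` (and
#' ideally `gene_id`) attributes. GTF 1-based inclusive coordinates are
#' converted to the internal 0-based half-open convention. Strand is
#' required: models are the unit of class-code classification, which is
#' strand-aware.
#'
#' @param path Path to a GTF file.
#' @return Named list of [transcript_model()] objects, keyed by id.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    stop("GTF line ", which(nf != 9L)[[1L]], ": expected 9 tab-separated ",
         "columns, found ", nf[nf != 9L][[1L]])
  }
  m <- do.call(rbind, fields)
  keep <- m[, 3L] == "exon"
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) return(list())
  tid <- gtf_attribute(m[, 9L], "transcript_id")
  if (any(is.na(tid))) {
    stop("GTF exon without transcript_id attribute (line ",
         which(keep)[which(is.na(tid))[[1L]]], ")")
  }
  gid <- gtf_attribute(m[, 9L], "gene_id")
  gid[is.na(gid)] <- tid[is.na(gid)]
  if (any(!m[, 7L] %in% c("+", "-"))) {
    stop("GTF exon with strand '", m[!m[, 7L] %in% c("+", "-"), 7L][[1L]],
         "': strand is required for classification")
  }
  start0 <- as.numeric(m[, 4L]) - 1  # GTF 1-based inclusive -> 0-based
  end0 <- as.numeric(m[, 5L])
  idx <- split(seq_along(tid), factor(tid, levels = unique(tid)))
  models <- lapply(idx, function(i) {
    transcript_model(tid[i[[1L]]], m[i[[1L]], 1L], m[i[[1L]], 7L],
                     cbind(start0[i], end0[i]), gene_id = gid[i[[1L]]])
  })
  chroms <- vapply(idx, function(i) length(unique(m[i, 1L])), integer(1))
  if (any(chroms > 1L)) {
    stop("transcript ", names(idx)[chroms > 1L][[1L]],
         " has exons on multiple chromosomes")
  }
  models
}

gtf_attribute <- function(attr, key) {
  pat <- paste0(".*", key, "[ =]+\"?([^\";]+)\"?.*")
  out <- ifelse(grepl(paste0(key, "[ =]"), attr), sub(pat, "\\1", attr), NA)
  out
}

#' Write transcript models as GTF exon features
#'
#' Inverse of [read_gtf()]: internal 0-based half-open intervals are
#' emitted as 1-based inclusive GTF coordinates.
#'
#' @param models Named list of `transcript_model` objects.
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path, source = "lncvine") {
  con <- file(path, "w")
  on.exit(close(con))
  for (mod in models) {
    ex <- mod$exons
    for (i in seq_len(nrow(ex))) {
      writeLines(paste(mod$chrom, source, "exon", ex[i, 1L] + 1, ex[i, 2L],
                       ".", mod$strand, ".",
                       sprintf("gene_id \"%s\"; transcript_id \"%s\";",
                               mod$gene_id, mod$id),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}
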