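#' Mean-expression filter for co-expression analysis
#'
#' Transcripts whose average consensus expression over conditions is below
#' `min_mean` FPKM are removed (the removal is strict `< min_mean`, so a
#' transcript averaging exactly 30 is retained).
#'
#' @param consensus Transcripts x conditions consensus matrix.
#' @param min_mean Retention threshold (FPKM).
#' @return Character vector of retained transcript ids.
#' @export
mean_filter <- function(consensus, min_mean = 30) {
  rownames(consensus)[rowMeans(consensus) >= min_mean]
}

#' Pearson co-expression edges between two transcript sets
#'
#' Computes the Pearson correlation of condition-consensus profiles for
#' every (lncRNA, partner) pair and keeps an edge when `r^2 >=
#' r2_threshold` (the default criterion; `criterion = "abs_r"` instead
#' keeps `|r| >= r2_threshold`). Negative-sign edges are retained and
#' labeled. Zero-variance profiles yield no edges (r undefined).
#'
#' @param lnc_ids,partner_ids Row ids of the two sets (both should have
#'   passed [mean_filter()]).
#' @param consensus Consensus matrix covering both sets (>= 3 conditions).
#' @param r2_threshold Edge threshold.
#' @param partner_kind Label stored on the edges (`"mRNA"`, `"TF"`,
#'   `"chloroplast_CDS"`, `"mitochondrial_CDS"`, ...).
#' @param criterion `"r2"` (default) or `"abs_r"`.
#' @return `data.frame` with `lncRNA_id`, `partner_id`, `partner_kind`,
#'   `r`, `r2`, `sign`.
#' @export
pearson_edges <- function(lnc_ids, partner_ids, consensus,
                          r2_threshold = 0.9, partner_kind = "mRNA",
                          criterion = c("r2", "abs_r")) {
  criterion <- match.arg(criterion)
  if (ncol(consensus) < 3L) stop("need at least 3 conditions")
  if (length(lnc_ids) == 0L || length(partner_ids) == 0L) {
    return(data.frame(lncRNA_id = character(0), partner_id = character(0),
                      partner_kind = character(0), r = numeric(0),
                      r2 = numeric(0), sign = character(0)))
  }
  cc <- suppressWarnings(
    cor(t(consensus[lnc_ids, , drop = FALSE]),
        t(consensus[partner_ids, , drop = FALSE])))
  idx <- which(!is.na(cc) &
               (if (criterion == "r2") cc^2 >= r2_threshold
                else abs(cc) >= r2_threshold),
               arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(data.frame(lncRNA_id = character(0), partner_id = character(0),
                      partner_kind = character(0), r = numeric(0),
                      r2 = numeric(0), sign = character(0)))
  }
  out <- data.frame(
    lncRNA_id = lnc_ids[idx[, 1L]], partner_id = partner_ids[idx[, 2L]],
    partner_kind = partner_kind, r = cc[idx], r2 = cc[idx]^2,
    sign = ifelse(cc[idx] >= 0, "+", "-"), stringsAsFactors = FALSE)
  out <- out[out$lncRNA_id != out$partner_id, , drop = FALSE]
  out[order(out$lncRNA_id, out$partner_id), , drop = FALSE]
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Bootstrap support of a co-expression edge
#'
#' Resamples the condition columns (the observational units of the
#' correlation) with replacement `n_runs` times and reports the fraction
#' of resamples whose correlation still meets the edge criterion.
#' Resamples with a zero-variance profile (r undefined) are skipped, i.e.
#' excluded from the denominator. Deterministic under a fixed seed.
#'
#' @param x,y Condition-consensus profiles of the two transcripts.
#' @param n_runs Number of bootstrap resamples (default 100).
#' @param r2_threshold Edge criterion applied to each resample.
#' @param seed Integer RNG seed.
#' @return Support fraction in \[0, 1\] (`NA` if every resample was
#'   degenerate).
#' @export
bootstrap_support <- function(x, y, n_runs = 100, r2_threshold = 0.9,
                              seed = 1L) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3L)
  with_seed(seed, {
    ok <- logical(0)
    for (b in seq_len(n_runs)) {
      take <- sample.int(n, n, replace = TRUE)
      r <- suppressWarnings(cor(x[take], y[take]))
      if (!is.na(r)) ok <- c(ok, r^2 >= r2_threshold)
    }
    if (length(ok) == 0L) NA_real_ else mean(ok)
  })
}

#' Add bootstrap support to an edge table
#'
#' @param edges Output of [pearson_edges()].
#' @param consensus Consensus matrix covering all edge endpoints.
#' @inheritParams bootstrap_support
#' @return `edges` with a `bootstrap_support` column. Each edge uses a
#'   sub-seed derived deterministically from `seed` and its row index.
#' @export
bootstrap_edges <- function(edges, consensus, n_runs = 100,
                            r2_threshold = 0.9, seed = 1L) {
  edges$bootstrap_support <- vapply(seq_len(nrow(edges)), function(i) {
    bootstrap_support(consensus[edges$lncRNA_id[[i]], ],
                      consensus[edges$partner_id[[i]], ],
                      n_runs = n_runs, r2_threshold = r2_threshold,
                      seed = (seed + i) %% .Machine$integer.max)
  }, numeric(1))
  edges
}

#' Transfer partner annotations to lncRNAs over co-expression edges
#'
#' Each lncRNA inherits the union of the annotation terms of its
#' co-expressed partners; every inherited term carries the list of
#' witness partners it came from. Partners missing from the term table
#' contribute nothing (they are logged via a message).
#'
#' @param edges Edge table ([pearson_edges()]).
#' @param term_table Term table ([read_term_table()]).
#' @return `data.frame` with `lncRNA_id`, `term`, `label`, `witnesses`
#'   (comma-separated partner ids).
#' @export
transfer_annotations <- function(edges, term_table) {
  missing <- setdiff(unique(edges$partner_id),
                     unique(term_table$transcript_id))
  if (length(missing) > 0L) {
    message(length(missing), " partners without annotation terms")
  }
  mg <- merge(edges[c("lncRNA_id", "partner_id")], term_table,
              by.x = "partner_id", by.y = "transcript_id")
  if (nrow(mg) == 0L) {
    return(data.frame(lncRNA_id = character(0), term = character(0),
                      label = character(0), witnesses = character(0)))
  }
  key <- paste(mg$lncRNA_id, mg$term, sep = "\r")
  wit <- vapply(split(mg$partner_id, key), function(p)
    paste(sort(unique(p)), collapse = ","), character(1))
  first <- mg[!duplicated(key), ]
  first <- first[order(paste(first$lncRNA_id, first$term, sep = "\r")), ]
  data.frame(lncRNA_id = first$lncRNA_id, term = first$term,
             label = first$label,
             witnesses = wit[order(names(wit))],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hypergeometric term enrichment
#'
#' Upper-tail hypergeometric test per term: the probability of observing
#' at least the seen number of term members in the selected set, given the
#' term's background frequency; BH-adjusted across terms.
#'
#' @param selected_ids Selected transcript ids (subset of background).
#' @param term_table Term table ([read_term_table()]).
#' @param background_ids Background transcript ids.
#' @return `data.frame` with `term`, `label`, `hits_selected`,
#'   `hits_background`, `p`, `fdr`, ordered by `p`.
#' @export
enrichment <- function(selected_ids, term_table, background_ids) {
  if (!all(selected_ids %in% background_ids)) {
    stop("selected ids must be a subset of the background")
  }
  tt <- term_table[term_table$transcript_id %in% background_ids, ]
  if (length(selected_ids) == 0L || nrow(tt) == 0L) {
    return(data.frame(term = character(0), label = character(0),
                      hits_selected = integer(0),
                      hits_background = integer(0), p = numeric(0),
                      fdr = numeric(0)))
  }
  N <- length(unique(background_ids))
  n <- length(unique(selected_ids))
  terms <- unique(tt$term)
  rows <- lapply(terms, function(tm) {
    members <- unique(tt$transcript_id[tt$term == tm])
    K <- length(members)
    k <- length(intersect(members, selected_ids))
    data.frame(term = tm, label = tt$label[tt$term == tm][[1L]],
               hits_selected = k, hits_background = K,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out[order(out$p, out$term), , drop = FALSE]
}

#' Local alignment of two nucleotide sequences
#'
#' Smith-Waterman local alignment (match +1, mismatch -2, gap -2.5 by
#' default), used as the internal fallback when external tabular hits are
#' not supplied. Coordinates are 1-based inclusive.
#'
#' @param a,b Nucleotide sequences.
#' @param match,mismatch,gap Scoring parameters.
#' @return List: `score`, `a_start`, `a_end`, `b_start`, `b_end`,
#'   `align_length` (aligned columns incl. gaps), `n_ident`, `n_gaps`,
#'   `identity` (identical columns / aligned columns).
#' @export
local_align <- function(a, b, match = 1, mismatch = -2, gap = -2.5) {
  res <- .sw_align(toupper(a), toupper(b), match, mismatch, gap)
  res$identity <- if (res$align_length > 0) {
    res$n_ident / res$align_length
  } else NA_real_
  res
}

#' Screen lncRNAs for organelle-genome homology
#'
#' Either filters an ingested tabular hit table or aligns every lncRNA
#' against every organelle CDS with the internal local aligner; retained
#' hits must have an alignment length strictly greater than
#' `min_align_len` nt.
#'
#' @param lnc_records `seq_set` of lncRNA candidates (ignored when `hits`
#'   is supplied).
#' @param organelle_records `seq_set` of organelle CDS sequences.
#' @param hits Optional ingested hit table ([read_blast_tab()]).
#' @param min_align_len Minimum alignment length (strict `>`).
#' @return `data.frame` with `lncRNA_id`, `organelle_id`, `align_length`,
#'   `identity`, `score`.
#' @export
organelle_homology <- function(lnc_records, organelle_records = NULL,
                               hits = NULL, min_align_len = 200) {
  if (!is.null(hits)) {
    keep <- hits$align_length > min_align_len
    return(data.frame(lncRNA_id = hits$query_id[keep],
                      organelle_id = hits$subject_id[keep],
                      align_length = hits$align_length[keep],
                      identity = hits$percent_identity[keep] / 100,
                      score = hits$bit_score[keep],
                      stringsAsFactors = FALSE, row.names = NULL))
  }
  stopifnot(!is.null(organelle_records))
  rows <- list()
  for (i in seq_len(nrow(lnc_records))) {
    for (j in seq_len(nrow(organelle_records))) {
      al <- local_align(lnc_records$seq[[i]], organelle_records$seq[[j]])
      if (al$align_length > min_align_len) {
        rows[[length(rows) + 1L]] <- data.frame(
          lncRNA_id = lnc_records$id[[i]],
          organelle_id = organelle_records$id[[j]],
          align_length = al$align_length, identity = al$identity,
          score = al$score, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(lncRNA_id = character(0), organelle_id = character(0),
                      align_length = numeric(0), identity = numeric(0),
                      score = numeric(0)))
  }
  do.call(rbind, rows)
}
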