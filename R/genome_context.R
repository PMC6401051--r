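CLASS_CODE_ORDER <- c("=", "c", "j", "e", "o", "i", "x", "s", "p", "u")

#' Assign transcripts to chromosomes from genome alignments
#'
#' Filters genome-alignment hits at per-cent identity > `min_identity`
#' (strict) and e-value < `max_evalue` (strict), then keeps the best
#' surviving hit per query, ordered by bit score (descending), e-value
#' (ascending), subject id, and s_start (both ascending). Subject strand
#' comes from the subject coordinate orientation.
#'
#' @param hits A hit table from [read_blast_tab()], queries being
#'   transcripts and subjects chromosomes.
#' @param min_identity Identity threshold (per cent, strict `>`).
#' @param max_evalue E-value threshold (strict `<`).
#' @return List with `placed` (data.frame `transcript_id`, `chrom`,
#'   `strand`, `start`, `end` — 0-based half-open subject interval) and
#'   `unplaced` (character vector of query ids with no surviving hit).
#' @export
assign_chromosome <- function(hits, min_identity = 90, max_evalue = 1e-10) {
  all_q <- unique(hits$query_id)
  ok <- hits$percent_identity > min_identity & hits$evalue < max_evalue
  h <- hits[ok, , drop = FALSE]
  if (nrow(h) > 0L) {
    h <- h[order(h$query_id, -h$bit_score, h$evalue, h$subject_id,
                 h$s_start), , drop = FALSE]
    h <- h[!duplicated(h$query_id), , drop = FALSE]
  }
  placed <- data.frame(
    transcript_id = h$query_id, chrom = h$subject_id,
    strand = ifelse(h$s_start <= h$s_end, "+", "-"),
    start = pmin(h$s_start, h$s_end) - 1,
    end = pmax(h$s_start, h$s_end),
    stringsAsFactors = FALSE)
  list(placed = placed, unplaced = setdiff(all_q, placed$transcript_id))
}

#' Chromosome distribution and density table
#'
#' @param loci `placed` data.frame from [assign_chromosome()] (or any
#'   data.frame with a `chrom` column).
#' @param chrom_lengths Named numeric vector of chromosome lengths (nt).
#' @return `data.frame` with `chrom`, `count`, `chrom_length`, `density`
#'   (count per Mbp) and `share` (per cent of placed transcripts; sums to
#'   100 when any are placed).
#' @export
density_and_distribution <- function(loci, chrom_lengths) {
  unknown <- setdiff(unique(loci$chrom), names(chrom_lengths))
  if (length(unknown) > 0L) {
    stop("locus on unknown chromosome: ", unknown[[1L]])
  }
  counts <- table(factor(loci$chrom, levels = names(chrom_lengths)))
  total <- sum(counts)
  data.frame(
    chrom = names(chrom_lengths),
    count = as.integer(counts),
    chrom_length = as.numeric(chrom_lengths),
    density = as.integer(counts) / (as.numeric(chrom_lengths) / 1e6),
    share = if (total > 0) 100 * as.integer(counts) / total else 0,
    stringsAsFactors = FALSE)
}

#' Transcript length histogram
#'
#' Left-open right-closed bins over `(0, e1], (e1, e2], ...` plus a final
#' open-ended bin above the last edge.
#'
#' @param lengths Numeric vector of transcript lengths (or a `seq_set`,
#'   whose `length` column is used).
#' @param bin_edges Strictly increasing positive edges.
#' @return Named integer vector of bin counts.
#' @export
length_histogram <- function(lengths,
                             bin_edges = c(250, 500, 1000, 2000, 4000)) {
  if (is.data.frame(lengths)) lengths <- lengths$length
  if (any(diff(bin_edges) <= 0)) {
    stop("bin edges must be strictly increasing")
  }
  breaks <- c(0, bin_edges, Inf)
  labels <- c(paste0("<=", bin_edges[[1L]]),
              paste0(head(bin_edges, -1L) + 1, "-", tail(bin_edges, -1L)),
              paste0(">", tail(bin_edges, 1L)))
  counts <- table(cut(lengths, breaks = breaks, right = TRUE,
                      labels = labels))
  setNames(as.integer(counts), labels)
}

interval_overlaps <- function(a_start, a_end, b_start, b_end) {
  a_start < b_end & b_start < a_end
}

any_exon_overlap <- function(ex_a, ex_b) {
  for (i in seq_len(nrow(ex_a))) {
    if (any(interval_overlaps(ex_a[i, 1L], ex_a[i, 2L],
                              ex_b[, 1L], ex_b[, 2L]))) return(TRUE)
  }
  FALSE
}

contained_in_any <- function(iv, set) {
  any(set[, 1L] <= iv[[1L]] & iv[[2L]] <= set[, 2L])
}

intron_key <- function(introns) {
  if (nrow(introns) == 0L) return(character(0))
  paste(introns[, 1L], introns[, 2L], sep = "-")
}

# Code of a query model relative to ONE reference model, or NA when no
# rule applies. Both models must share a coordinate convention.
code_vs_reference <- function(query, ref, runon_window = 2000) {
  if (query$chrom != ref$chrom) return(NA_character_)
  qe <- query$exons; re <- ref$exons
  qi <- model_introns(query); ri <- model_introns(ref)
  r_span <- c(re[1L, 1L], re[nrow(re), 2L])
  same <- query$strand == ref$strand
  exonic <- any_exon_overlap(qe, re)
  # overlap is judged on query exons (a query intron spanning the
  # reference does not count as overlap)
  span_overlap <- any(interval_overlaps(qe[, 1L], qe[, 2L],
                                        r_span[[1L]], r_span[[2L]]))

  if (same) {
    # '=': identical intron chain (multi-exon) or identical coordinates
    # (single-exon)
    if (nrow(qe) > 1L && nrow(re) > 1L &&
        identical(intron_key(qi), intron_key(ri))) return("=")
    if (nrow(qe) == 1L && nrow(re) == 1L &&
        qe[1L, 1L] == re[1L, 1L] && qe[1L, 2L] == re[1L, 2L]) return("=")
    # 'c': all query exons within reference exons, query intron chain a
    # contiguous sub-chain of the reference's
    all_in_exons <- all(vapply(seq_len(nrow(qe)), function(i)
      contained_in_any(qe[i, ], re), logical(1)))
    if (all_in_exons) {
      qk <- intron_key(qi); rk <- intron_key(ri)
      sub_chain <- length(qk) == 0L ||
        (length(qk) <= length(rk) &&
         any(vapply(seq_len(length(rk) - length(qk) + 1L), function(s)
           identical(qk, rk[s:(s + length(qk) - 1L)]), logical(1))))
      if (sub_chain) return("c")
    }
    # 'j': shares at least one intron (splice junction) with the reference
    if (length(intersect(intron_key(qi), intron_key(ri))) > 0L) return("j")
    # 'e': single-exon query overlapping both a reference exon and a
    # reference intron (possible pre-mRNA fragment)
    if (nrow(qe) == 1L && exonic && nrow(ri) > 0L &&
        any(interval_overlaps(qe[1L, 1L], qe[1L, 2L],
                              ri[, 1L], ri[, 2L]))) return("e")
    # 'o': generic same-strand exonic overlap
    if (exonic) return("o")
    # 'i': all query exons within a single reference intron
    if (nrow(ri) > 0L) {
      for (k in seq_len(nrow(ri))) {
        if (all(ri[k, 1L] <= qe[, 1L] & qe[, 2L] <= ri[k, 2L])) return("i")
      }
    }
    # 'p': run-on fragment — no overlap, query within the run-on window
    # of the reference transcript. The window applies on either side:
    # a direction-free rule keeps classification invariant under joint
    # strand relabeling, which a "downstream of the 3' end only" rule
    # cannot be.
    if (!span_overlap) {
      gap_r <- qe[1L, 1L] - r_span[[2L]]
      gap_l <- r_span[[1L]] - qe[nrow(qe), 2L]
      if ((gap_r >= 0 && gap_r <= runon_window) ||
          (gap_l >= 0 && gap_l <= runon_window)) return("p")
    }
    return(NA_character_)
  }
  # opposite strand
  if (exonic) return("x")
  if (span_overlap) return("s")
  NA_character_
}

#' Classify a transcript model against reference gene models
#'
#' Assigns a single-character class code describing the genomic relation
#' of `model` to the reference annotation, in the style of Cuffcompare:
#' `=` complete intron-chain match; `c` contained; `j` shared splice
#' junction (potentially novel isoform); `e` single-exon overlap of both a
#' reference exon and intron (pre-mRNA fragment); `o` generic same-strand
#' exonic overlap; `i` entirely within a reference intron; `x`
#' opposite-strand exonic overlap (antisense); `s` opposite-strand overlap
#' confined to reference introns; `p` possible polymerase run-on fragment
#' (no overlap, within `runon_window` nt of a reference transcript on
#' either side); `u` unknown/intergenic. When several references match, the
#' most specific code in the precedence order
#' `=, c, j, e, o, i, x, s, p` wins; ties go to the lexicographically
#' smallest reference id.
#'
#' @param model A `transcript_model` query.
#' @param reference_models Named list of `transcript_model` references.
#' @param runon_window Distance (nt) defining the `p` run-on window.
#' @return `data.frame` row with `transcript_id`, `code`, `reference_id`
#'   (empty string for `u`).
#' @export
classify_transcript <- function(model, reference_models,
                                runon_window = 2000) {
  best_rank <- Inf; best_code <- "u"; best_ref <- ""
  ref_ids <- vapply(reference_models, `[[`, character(1), "id")
  for (k in order(ref_ids)) {
    ref <- reference_models[[k]]
    code <- code_vs_reference(model, ref, runon_window)
    if (is.na(code)) next
    rank <- match(code, CLASS_CODE_ORDER)
    if (rank < best_rank) {
      best_rank <- rank; best_code <- code; best_ref <- ref$id
    }
  }
  data.frame(transcript_id = model$id, code = best_code,
             reference_id = best_ref, stringsAsFactors = FALSE)
}

#' Classify many transcript models
#'
#' @param models Named list of `transcript_model` queries.
#' @inheritParams classify_transcript
#' @return `data.frame` with one row per query model.
#' @export
classify_transcripts <- function(models, reference_models,
                                 runon_window = 2000) {
  do.call(rbind, lapply(models, classify_transcript,
                        reference_models = reference_models,
                        runon_window = runon_window))
}

#' Class-code percentage summary
#'
#' @param results Output of [classify_transcripts()].
#' @return `data.frame` with `code`, `count`, `percent` (percentages over
#'   classified transcripts, summing to 100 when non-empty).
#' @export
class_code_summary <- function(results) {
  if (nrow(results) == 0L) {
    return(data.frame(code = character(0), count = integer(0),
                      percent = numeric(0)))
  }
  counts <- table(factor(results$code, levels = CLASS_CODE_ORDER))
  counts <- counts[counts > 0]
  data.frame(code = names(counts), count = as.integer(counts),
             percent = 100 * as.integer(counts) / nrow(results),
             stringsAsFactors = FALSE)
}

#' Build single-exon query models from genome placements
#'
#' Genome placement yields single-exon models unless a GTF of spliced
#' alignments is supplied; this converts [assign_chromosome()] output into
#' classifiable models.
#'
#' @param placed `placed` data.frame from [assign_chromosome()].
#' @return Named list of single-exon `transcript_model` objects.
#' @export
placements_to_models <- function(placed) {
  out <- lapply(seq_len(nrow(placed)), function(i) {
    transcript_model(placed$transcript_id[[i]], placed$chrom[[i]],
                     placed$strand[[i]],
                     cbind(placed$start[[i]], placed$end[[i]]))
  })
  setNames(out, placed$transcript_id)
}
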