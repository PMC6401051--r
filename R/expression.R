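#' Consensus expression per condition
#'
#' Collapses replicate samples into one consensus value per condition
#' (tissue x developmental stage). The default aggregator is the
#' arithmetic mean of the replicate FPKM values; the median is available
#' as a robust alternative.
#'
#' @param fpkm Numeric matrix, transcripts x samples.
#' @param samples Sample sheet data.frame with `sample` and `condition`
#'   columns (see [read_expression()]).
#' @param fun Aggregation: `"mean"` (default) or `"median"`.
#' @return Numeric matrix, transcripts x conditions (conditions in order
#'   of first appearance in the sample sheet).
#' @export
consensus_expression <- function(fpkm, samples, fun = c("mean", "median")) {
  fun <- match.arg(fun)
  conds <- unique(samples$condition)
  out <- vapply(conds, function(cc) {
    cols <- samples$sample[samples$condition == cc]
    if (length(cols) == 0L) stop("condition with zero samples: ", cc)
    sub <- fpkm[, cols, drop = FALSE]
    if (fun == "mean") rowMeans(sub) else apply(sub, 1L, stats::median)
  }, numeric(nrow(fpkm)))
  out <- matrix(out, nrow = nrow(fpkm),
                dimnames = list(rownames(fpkm), conds))
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Direct implementation of the BH step-up procedure:
#' `fdr_(i) = min_{j >= i} min(1, m * p_(j) / j)` over the ranked
#' p-values.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be in [0, 1]")
  }
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

welch_p <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * pt(-abs(tstat), df)
  # degenerate: zero variance in both groups
  p[se2 == 0] <- ifelse(m1[se2 == 0] == m2[se2 == 0], 1, 0)
  p
}

# Two-sample t with limma-style variance moderation: per-transcript
# pooled variances are shrunk toward a common prior estimated across
# transcripts (empirical Bayes), gaining the degrees of freedom that
# n = 3 designs lack. Falls back to the plain computation when every
# variance is zero (noiseless data).
moderated_p <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  df <- n1 + n2 - 2L
  s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / df
  if (all(s2 == 0) || length(s2) < 2L) return(welch_p(x1, x2))
  sq <- limma::squeezeVar(s2, df)
  se <- sqrt(sq$var.post * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  p <- 2 * pt(-abs(tstat), df + sq$df.prior)
  p[se == 0] <- ifelse(m1[se == 0] == m2[se == 0], 1, 0)
  p
}

#' Differential-expression filter over all condition pairs
#'
#' For every pair of conditions the log2 fold change is computed from the
#' consensus values with a pseudocount of 1 FPKM, and a two-sided t-test
#' is run on log2(FPKM + 1) across replicates (or p-values are taken from
#' `p_table` when the replicate structure does not support a test). By
#' default the test moderates per-transcript variances across transcripts
#' (limma-style empirical Bayes shrinkage) — with 3 replicates an
#' unmoderated test has too few degrees of freedom to clear an FDR of
#' 0.001 reliably even at 8-fold changes; `var_moderation = FALSE`
#' selects a plain Welch t-test instead. P-values are BH-adjusted per
#' comparison across transcripts. A
#' transcript is flagged differentially expressed when any comparison
#' shows at least `min_fold`-fold change at FDR <= `max_fdr`.
#'
#' @inheritParams consensus_expression
#' @param min_fold Fold-change threshold (default 4).
#' @param max_fdr FDR threshold (default 0.001).
#' @param p_table Optional ingested p-values: data.frame with columns
#'   `transcript_id`, `comparison` (`"condA|condB"`), `p_value`.
#' @param var_moderation Moderate variances across transcripts (default
#'   `TRUE`).
#' @return List with `results` (per transcript x comparison: `log2fc`,
#'   `p_value`, `fdr`, `is_de`) and `de_transcripts` (ids flagged in any
#'   comparison).
#' @export
de_filter <- function(fpkm, samples, min_fold = 4, max_fdr = 0.001,
                      p_table = NULL, var_moderation = TRUE) {
  cons <- consensus_expression(fpkm, samples)
  conds <- colnames(cons)
  if (length(conds) < 2L) stop("need at least two conditions")
  reps <- table(samples$condition)
  if (is.null(p_table) && any(reps < 2L)) {
    stop("fewer than 2 replicates in some condition and no ingested ",
         "p-value table supplied")
  }
  lg <- log2(fpkm + 1)
  min_l2 <- log2(min_fold)
  pieces <- list()
  for (i in seq_len(length(conds) - 1L)) {
    for (j in seq(i + 1L, length(conds))) {
      cmp <- paste(conds[[i]], conds[[j]], sep = "|")
      l2fc <- log2((cons[, i] + 1) / (cons[, j] + 1))
      if (is.null(p_table)) {
        c1 <- samples$sample[samples$condition == conds[[i]]]
        c2 <- samples$sample[samples$condition == conds[[j]]]
        p <- if (var_moderation) {
          moderated_p(lg[, c1, drop = FALSE], lg[, c2, drop = FALSE])
        } else {
          welch_p(lg[, c1, drop = FALSE], lg[, c2, drop = FALSE])
        }
      } else {
        sub <- p_table[p_table$comparison == cmp, ]
        p <- sub$p_value[match(rownames(fpkm), sub$transcript_id)]
        if (anyNA(p)) stop("ingested p-table missing transcripts for ", cmp)
      }
      fdr <- bh_adjust(p)
      pieces[[cmp]] <- data.frame(
        transcript_id = rownames(fpkm), comparison = cmp, log2fc = l2fc,
        p_value = p, fdr = fdr,
        is_de = abs(l2fc) >= min_l2 & fdr <= max_fdr,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  results <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  de_ids <- unique(results$transcript_id[results$is_de])
  list(results = results, de_transcripts = de_ids)
}

EXPRESSION_BINS <- data.frame(
  label = c("not expressed", "extremely low", "very low", "low",
            "moderate", "high", "very high", "extremely high"),
  upper = c(0, 5, 20, 50, 100, 500, 1000, Inf))

#' Categorize FPKM values into abundance bins
#'
#' The seven groups: extremely low (0, 5\], very low (5, 20\], low
#' (20, 50\], moderate (50, 100\], high (100, 500\], very high
#' (500, 1000\], extremely high (> 1000); exactly 0 is "not expressed".
#'
#' @param fpkm Numeric vector of FPKM values (>= 0).
#' @return Factor of bin labels, levels ordered by abundance.
#' @export
bin_expression <- function(fpkm) {
  if (any(fpkm < 0)) stop("negative FPKM value")
  idx <- findInterval(fpkm, EXPRESSION_BINS$upper, left.open = TRUE) + 1L
  factor(EXPRESSION_BINS$label[idx], levels = EXPRESSION_BINS$label)
}

#' Tissue/developmental-stage specificity index
#'
#' The per-condition index is the quotient of the consensus expression in
#' that condition and the sum of consensus values over all conditions; it
#' ranges from 1/N (uniform, housekeeping-like) to 1 (expressed in one
#' condition only). A transcript is specific when its maximum index
#' reaches `threshold` (default 0.7).
#'
#' @param consensus_row Named numeric vector of per-condition consensus
#'   values (>= 0, at least two conditions).
#' @param threshold Specificity cutoff.
#' @return List with `indices` (per condition; `NA` for an all-zero row),
#'   `max_index`, `condition` (argmax), `is_specific`, `all_zero`.
#' @export
specificity_index <- function(consensus_row, threshold = 0.7) {
  if (length(consensus_row) < 2L) stop("need at least two conditions")
  if (any(consensus_row < 0)) stop("negative consensus value")
  total <- sum(consensus_row)
  if (total == 0) {
    return(list(indices = rep(NA_real_, length(consensus_row)),
                max_index = NA_real_, condition = NA_character_,
                is_specific = FALSE, all_zero = TRUE))
  }
  idx <- consensus_row / total
  k <- which.max(idx)
  list(indices = idx, max_index = unname(idx[[k]]),
       condition = names(consensus_row)[[k]] %||% as.character(k),
       is_specific = unname(idx[[k]]) >= threshold, all_zero = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specificity table for a consensus matrix
#'
#' @param consensus Transcripts x conditions consensus matrix.
#' @inheritParams specificity_index
#' @return `data.frame` with `transcript_id`, `max_index`, `condition`,
#'   `is_specific`, `all_zero`.
#' @export
specificity_table <- function(consensus, threshold = 0.7) {
  rows <- lapply(seq_len(nrow(consensus)), function(i) {
    res <- specificity_index(consensus[i, ], threshold)
    data.frame(transcript_id = rownames(consensus)[[i]],
               max_index = res$max_index, condition = res$condition,
               is_specific = res$is_specific, all_zero = res$all_zero,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
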