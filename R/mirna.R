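# Pairing state of (miRNA base, transcript base), DNA alphabet:
# Watson-Crick, G:U wobble (G~T / T~G), or mismatch.
pair_state <- function(m, t) {
  wc <- (m == "A" & t == "T") | (m == "T" & t == "A") |
        (m == "G" & t == "C") | (m == "C" & t == "G")
  gu <- (m == "G" & t == "T") | (m == "T" & t == "G")
  ifelse(wc, "match", ifelse(gu, "GU", "mismatch"))
}

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

#' Score a miRNA/transcript-window duplex
#'
#' Ungapped plant-style penalty scoring of an antiparallel duplex between
#' a mature miRNA (5'->3') and a same-length transcript window (5'->3'):
#' per miRNA position, a Watson-Crick pair scores 0, a G:U wobble 0.5 and
#' a mismatch 1.0; penalties are doubled in the seed-critical region,
#' miRNA positions 2-13. The total penalty is the site score (lower is
#' better).
#'
#' @param mirna Mature miRNA sequence (DNA alphabet, 5'->3').
#' @param window Transcript window of the same length (5'->3').
#' @return List with `score` (total penalty) and `states` (per miRNA
#'   position 1..L: `"match"`, `"GU"`, `"mismatch"`).
#' @examples
#' score_duplex("ATGC", revcomp("ATGC"))  # perfect duplex, score 0
#' @export
score_duplex <- function(mirna, window) {
  m <- chars(toupper(mirna)); w <- chars(toupper(window))
  L <- length(m)
  if (length(w) != L) {
    stop("window length must equal miRNA length in ungapped mode")
  }
  # miRNA position i pairs the transcript base at window position L-i+1
  partner <- rev(w)
  states <- pair_state(m, partner)
  pen <- c(match = 0, GU = 0.5, mismatch = 1)[states]
  mult <- ifelse(seq_len(L) >= 2 & seq_len(L) <= 13, 2, 1)
  list(score = sum(pen * mult), states = unname(states))
}

# Penalty lookup used by the vectorized window scan.
duplex_penalty_map <- local({
  bases <- c("A", "C", "G", "T", "N")
  grid <- expand.grid(m = bases, t = bases, stringsAsFactors = FALSE)
  st <- pair_state(grid$m, grid$t)
  setNames(c(match = 0, GU = 0.5, mismatch = 1)[st],
           paste0(grid$m, grid$t))
})

scan_duplex_scores <- function(mirna, transcript) {
  m <- chars(toupper(mirna)); tch <- chars(toupper(transcript))
  L <- length(m); n <- length(tch)
  ns <- n - L + 1L
  if (ns < 1L) return(numeric(0))
  # window position j holds the partner of miRNA position L-j+1
  idx <- outer(seq_len(ns) - 1L, seq_len(L), `+`)
  key <- paste0(rep(rev(m), each = ns), tch[idx])
  pen <- matrix(duplex_penalty_map[key], nrow = ns)
  mult <- rev(ifelse(seq_len(L) >= 2 & seq_len(L) <= 13, 2, 1))
  as.numeric(pen %*% mult)
}

collapse_overlaps <- function(df, value, start, width) {
  # keep best-scoring (lowest value) sites, ties to the leftmost, greedy
  # non-overlap selection
  o <- order(df[[value]], df[[start]])
  taken <- logical(0); keep <- integer(0)
  ivs <- matrix(numeric(0), ncol = 2)
  for (i in o) {
    s <- df[[start]][[i]]; e <- s + width - 1L
    if (nrow(ivs) == 0L || all(e < ivs[, 1L] | s > ivs[, 2L])) {
      keep <- c(keep, i)
      ivs <- rbind(ivs, c(s, e))
    }
  }
  df[sort(keep), , drop = FALSE]
}

#' Find miRNA target sites on a transcript
#'
#' Scans every window of miRNA length with [score_duplex()] and reports
#' windows whose penalty is at most `max_score`; overlapping sites of one
#' miRNA are collapsed to the best-scoring (ties to the leftmost).
#'
#' @param mirna_id,mirna Mature miRNA id and sequence.
#' @param transcript_id,transcript Transcript id and sequence.
#' @param max_score Maximum penalty for a reported site (default 3.0).
#' @return `data.frame` with `mirna_id`, `transcript_id`, `start`, `end`
#'   (0-based half-open window on the transcript), `score`,
#'   `kind = "target"`.
#' @export
find_target_sites <- function(mirna_id, mirna, transcript_id, transcript,
                              max_score = 3.0) {
  L <- nchar(mirna)
  if (nchar(transcript) < L) stop("transcript shorter than miRNA")
  sc <- scan_duplex_scores(mirna, transcript)
  hit <- which(sc <= max_score)
  out <- data.frame(mirna_id = rep(mirna_id, length(hit)),
                    transcript_id = rep(transcript_id, length(hit)),
                    start = hit - 1L, end = hit - 1L + L,
                    score = sc[hit], kind = rep("target", length(hit)),
                    stringsAsFactors = FALSE)
  if (nrow(out) > 1L) out <- collapse_overlaps(out, "score", "start", L)
  row.names(out) <- NULL
  out
}

# Pairing strength of (miRNA base, transcript base): G:C = 3, A:T = 2,
# G:U wobble = 1, mismatch = 0.
pair_strength <- function(m, t) {
  st <- pair_state(m, t)
  gc <- (m == "G" & t == "C") | (m == "C" & t == "G")
  ifelse(st == "match", ifelse(gc, 3, 2), ifelse(st == "GU", 1, 0))
}

#' Find endogenous target-mimic (eTM) sites
#'
#' Scans windows of miRNA length + `bulge_len` for the eTM geometry: the
#' extra transcript nucleotides form a bulge positioned between the bases
#' pairing miRNA positions 10 and 11 (the cleavage site), and the flanks
#' pair without gaps or mismatches: every miRNA position must form a
#' Watson-Crick or G:U pair. A candidate is accepted when its pairing
#' ratio —
#' `pairing_score / perfect_score`, with G:C = 3, A:T = 2, G:U = 1 summed
#' over the flank positions and `perfect_score` that of a
#' full-length perfect duplex — reaches `min_pairing_ratio`. Overlapping
#' candidates are collapsed to the best ratio (ties to the leftmost).
#'
#' @inheritParams find_target_sites
#' @param min_pairing_ratio Acceptance threshold (default 0.7).
#' @param bulge_len Bulge length in nt (default 3, the characteristic eTM
#'   bulge; 2-4 may be allowed by flag).
#' @return `data.frame` with `mirna_id`, `transcript_id`, `start`, `end`,
#'   `bulge_start` (0-based), `pairing_ratio`, `kind = "eTM"`.
#' @export
find_etm_sites <- function(mirna_id, mirna, transcript_id, transcript,
                           min_pairing_ratio = 0.7, bulge_len = 3L) {
  m <- chars(toupper(mirna)); L <- length(m)
  if (L < 12L) stop("miRNA too short for the 10/11 bulge geometry")
  W <- L + bulge_len
  tch <- chars(toupper(transcript))
  if (length(tch) < W) stop("transcript shorter than miRNA + bulge")
  perfect <- sum(ifelse(m %in% c("G", "C"), 3, 2))
  ns <- length(tch) - W + 1L
  # antiparallel geometry: miRNA position i pairs the transcript base at
  # window offset W-i+1 for i <= 10 (3' side of the bulge) and L-i+1 for
  # i >= 11 (5' side); the bulge occupies window offsets L-9..L-10+bulge
  off <- ifelse(seq_len(L) <= 10L, W - seq_len(L), L - seq_len(L))
  idx <- outer(seq_len(ns), off, `+`)  # 1-based transcript positions
  part <- matrix(tch[idx], nrow = ns)
  mm <- matrix(rep(m, each = ns), nrow = ns)
  strength <- matrix(pair_strength(mm, part), nrow = ns)
  ratio <- rowSums(strength) / perfect
  # both flanks must form contiguous duplexes: every miRNA position pairs
  # (Watson-Crick or G:U); the ratio then screens out wobble/A:U-weak
  # duplexes. Mismatch tolerance would admit chance matches on random
  # sequence, defeating the bulge geometry as a classifier.
  all_paired <- rowSums(strength > 0) == L
  hit <- which(all_paired & ratio >= min_pairing_ratio)
  if (length(hit) == 0L) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      start = integer(0), end = integer(0),
                      bulge_start = integer(0), pairing_ratio = numeric(0),
                      kind = character(0)))
  }
  out <- data.frame(
    mirna_id = mirna_id, transcript_id = transcript_id,
    start = hit - 1L, end = hit - 1L + W,
    bulge_start = hit - 1L + L - 10L, pairing_ratio = ratio[hit],
    kind = "eTM", stringsAsFactors = FALSE)
  out$neg_ratio <- -out$pairing_ratio
  out <- collapse_overlaps(out, "neg_ratio", "start", W)
  out$neg_ratio <- NULL
  row.names(out) <- NULL
  out
}

#' Foldback (hairpin) paired fraction by base-pair maximization
#'
#' Nussinov-style maximization of nested Watson-Crick + G:U pairs with a
#' minimum hairpin loop of `min_loop` unpaired nt; the paired fraction is
#' `2 * pairs / length`. This is a documented stand-in for thermodynamic
#' folding: it captures foldback capacity, not free energy.
#'
#' @param seq Nucleotide sequence.
#' @param min_loop Minimum loop length (default 3).
#' @return Paired fraction in \[0, 1\].
#' @export
foldback_fraction <- function(seq, min_loop = 3L) {
  n <- nchar(seq)
  if (n == 0L) return(0)
  2 * .nussinov_pairs(toupper(seq), min_loop) / n
}

#' Find candidate miRNA precursors among lncRNAs
#'
#' Searches each hairpin (stem-loop) sequence against each lncRNA with
#' the internal local aligner (or filters ingested tabular hits whose
#' queries are hairpins). Matches must reach `min_identity` over the
#' aligned columns and cover at least `min_coverage` of the hairpin. The
#' foldback paired fraction of the matched lncRNA segment is reported
#' (not filtered on).
#'
#' @param lnc_records `seq_set` of lncRNA candidates.
#' @param hairpin_records `seq_set` of hairpin sequences.
#' @param min_identity Identity threshold (fraction).
#' @param min_coverage Hairpin coverage threshold (fraction).
#' @param hits Optional ingested hit table (queries = hairpins,
#'   subjects = lncRNAs).
#' @param min_loop Minimum loop for the foldback check.
#' @return `data.frame` with `hairpin_id`, `lncRNA_id`, `start`, `end`
#'   (0-based half-open on the lncRNA), `identity`, `coverage`,
#'   `foldback_paired_fraction`.
#' @export
find_precursors <- function(lnc_records, hairpin_records,
                            min_identity = 0.95, min_coverage = 0.95,
                            hits = NULL, min_loop = 3L) {
  if (nrow(hairpin_records) == 0L) stop("hairpin set is empty")
  lnc_seq <- setNames(lnc_records$seq, lnc_records$id)
  rows <- list()
  add_row <- function(hid, lid, s, e, ident, cov) {
    seg <- substr(lnc_seq[[lid]], s + 1L, e)
    rows[[length(rows) + 1L]] <<- data.frame(
      hairpin_id = hid, lncRNA_id = lid, start = s, end = e,
      identity = ident, coverage = cov,
      foldback_paired_fraction = foldback_fraction(seg, min_loop),
      stringsAsFactors = FALSE)
  }
  if (!is.null(hits)) {
    hp_len <- setNames(hairpin_records$length, hairpin_records$id)
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      if (!h$query_id %in% names(hp_len) ||
          !h$subject_id %in% names(lnc_seq)) next
      ident <- h$percent_identity / 100
      cov <- h$align_length / hp_len[[h$query_id]]
      if (ident >= min_identity && cov >= min_coverage) {
        add_row(h$query_id, h$subject_id,
                min(h$s_start, h$s_end) - 1L, max(h$s_start, h$s_end),
                ident, cov)
      }
    }
  } else {
    for (j in seq_len(nrow(hairpin_records))) {
      hp <- hairpin_records[j, ]
      for (i in seq_len(nrow(lnc_records))) {
        al <- local_align(hp$seq, lnc_records$seq[[i]])
        if (al$align_length == 0L) next
        cov <- (al$a_end - al$a_start + 1L) / hp$length
        if (al$identity >= min_identity && cov >= min_coverage) {
          add_row(hp$id, lnc_records$id[[i]], al$b_start - 1L, al$b_end,
                  al$identity, cov)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(hairpin_id = character(0), lncRNA_id = character(0),
                      start = integer(0), end = integer(0),
                      identity = numeric(0), coverage = numeric(0),
                      foldback_paired_fraction = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Summarize per-lncRNA interaction roles
#'
#' @param targets Target-site table ([find_target_sites()] rows,
#'   transcripts being lncRNAs).
#' @param etms eTM table ([find_etm_sites()]).
#' @param precursors Precursor table ([find_precursors()]).
#' @return List with `roles` (data.frame `lncRNA_id`, logical `target`,
#'   `precursor`, `eTM`) and `overlaps` (named counts for the Venn
#'   summary, including the pairwise and triple intersections).
#' @export
classify_interactions <- function(targets, etms, precursors) {
  t_ids <- unique(targets$transcript_id)
  e_ids <- unique(etms$transcript_id)
  p_ids <- unique(precursors$lncRNA_id)
  ids <- sort(unique(c(t_ids, e_ids, p_ids)))
  roles <- data.frame(lncRNA_id = ids, target = ids %in% t_ids,
                      precursor = ids %in% p_ids, eTM = ids %in% e_ids,
                      stringsAsFactors = FALSE)
  overlaps <- c(
    target = length(t_ids), precursor = length(p_ids),
    eTM = length(e_ids),
    target_precursor = length(intersect(t_ids, p_ids)),
    precursor_eTM = length(intersect(p_ids, e_ids)),
    target_eTM = length(intersect(t_ids, e_ids)),
    target_precursor_eTM = length(intersect(intersect(t_ids, p_ids),
                                            e_ids)))
  list(roles = roles, overlaps = overlaps)
}

#' Assemble the lncRNA-miRNA-mRNA interaction network
#'
#' Nodes are typed (`lncRNA`, `miRNA`, `mRNA`, ...) and edges carry their
#' origin (`coexpression`, `target`, `precursor`, `eTM`). When an
#' explicit node table is supplied, any edge endpoint missing from it is
#' an error (dangling edge).
#'
#' @param coexpr_edges Co-expression edge table ([pearson_edges()]); may
#'   be `NULL`.
#' @param targets,etms,precursors Interaction tables; any may be `NULL`.
#' @param nodes Optional data.frame (`id`, `type`) declaring the node
#'   universe.
#' @return An `igraph` graph with vertex attribute `type` and edge
#'   attribute `kind`.
#' @export
build_network <- function(coexpr_edges = NULL, targets = NULL,
                          etms = NULL, precursors = NULL, nodes = NULL) {
  ed <- list()
  if (!is.null(coexpr_edges) && nrow(coexpr_edges) > 0L) {
    ed$coexpr <- data.frame(from = coexpr_edges$lncRNA_id,
                            to = coexpr_edges$partner_id,
                            kind = "coexpression",
                            to_type = coexpr_edges$partner_kind,
                            from_type = "lncRNA",
                            stringsAsFactors = FALSE)
  }
  if (!is.null(targets) && nrow(targets) > 0L) {
    ed$target <- data.frame(from = targets$mirna_id,
                            to = targets$transcript_id, kind = "target",
                            to_type = "lncRNA", from_type = "miRNA",
                            stringsAsFactors = FALSE)
  }
  if (!is.null(etms) && nrow(etms) > 0L) {
    ed$etm <- data.frame(from = etms$mirna_id, to = etms$transcript_id,
                         kind = "eTM", to_type = "lncRNA",
                         from_type = "miRNA", stringsAsFactors = FALSE)
  }
  if (!is.null(precursors) && nrow(precursors) > 0L) {
    ed$prec <- data.frame(from = precursors$hairpin_id,
                          to = precursors$lncRNA_id, kind = "precursor",
                          to_type = "lncRNA", from_type = "miRNA",
                          stringsAsFactors = FALSE)
  }
  edges <- if (length(ed) > 0L) do.call(rbind, ed) else
    data.frame(from = character(0), to = character(0),
               kind = character(0), to_type = character(0),
               from_type = character(0))
  inferred <- unique(data.frame(
    id = c(edges$from, edges$to), type = c(edges$from_type, edges$to_type),
    stringsAsFactors = FALSE))
  if (is.null(nodes)) {
    nodes <- inferred
  } else {
    dangling <- setdiff(inferred$id, nodes$id)
    if (length(dangling) > 0L) {
      stop("dangling edge endpoint not in node table: ", dangling[[1L]])
    }
  }
  dup <- duplicated(nodes$id)
  nodes <- nodes[!dup, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[c("from", "to", "kind")], directed = FALSE, vertices = nodes)
  g
}

#' Write a network as edge-list TSV and GraphML
#'
#' @param graph Output of [build_network()].
#' @param prefix Output path prefix; writes `<prefix>_edges.tsv` and
#'   `<prefix>.graphml`.
#' @return Named character vector of the written paths, invisibly.
#' @export
export_network <- function(graph, prefix) {
  el <- igraph::as_data_frame(graph, what = "edges")
  tsv <- paste0(prefix, "_edges.tsv")
  write_tsv(el, tsv)
  gml <- paste0(prefix, ".graphml")
  igraph::write_graph(graph, gml, format = "graphml")
  invisible(c(edges = tsv, graphml = gml))
}
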