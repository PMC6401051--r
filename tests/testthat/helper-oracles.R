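# Independent brute-force oracles. These deliberately re-derive results
# by direct enumeration (position sets, codon walks, tail sums) rather
# than sharing any interval/vector arithmetic with the package.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
}

# exhaustive codon walk over all six frames; incomplete ORFs counted
oracle_max_orf_aa <- function(seq) {
  best <- 0L
  for (s in c(seq, oracle_revcomp(seq))) {
    n <- nchar(s)
    for (off in 0:2) {
      n_cod <- (n - off) %/% 3L
      if (n_cod < 1L) next
      at <- off + 1L + 3L * (seq_len(n_cod) - 1L)
      cods <- substring(s, at, at + 2L)
      for (i in seq_len(n_cod)) {
        if (cods[[i]] != "ATG") next
        aa <- 0L
        j <- i
        while (j <= n_cod) {
          if (j > i && cods[[j]] %in% c("TAA", "TAG", "TGA")) break
          aa <- aa + 1L
          j <- j + 1L
        }
        best <- max(best, aa)
      }
    }
  }
  best
}

# class-code oracle on integer position sets (1-based genomic positions)
oracle_class_code <- function(q, r, runon = 2000) {
  if (q$chrom != r$chrom) return(NA_character_)
  pos <- function(ex) unlist(lapply(seq_len(nrow(ex)), function(i)
    seq(ex[i, 1L] + 1L, ex[i, 2L])))
  ikey <- function(m) {
    ex <- m$exons
    if (nrow(ex) < 2L) return(character(0))
    vapply(seq_len(nrow(ex) - 1L), function(i)
      paste(ex[i, 2L], ex[i + 1L, 1L]), character(1))
  }
  qpos <- pos(q$exons); rpos <- pos(r$exons)
  rspan <- seq(min(rpos), max(rpos))
  rint_sets <- {
    ex <- r$exons
    if (nrow(ex) < 2L) list() else
      lapply(seq_len(nrow(ex) - 1L), function(i) {
        if (ex[i + 1L, 1L] > ex[i, 2L])
          seq(ex[i, 2L] + 1L, ex[i + 1L, 1L]) else integer(0)
      })
  }
  rint_pos <- unlist(rint_sets)
  qk <- ikey(q); rk <- ikey(r)
  same <- q$strand == r$strand
  exonic <- any(qpos %in% rpos)
  if (same) {
    if (nrow(q$exons) > 1L && nrow(r$exons) > 1L &&
        length(qk) == length(rk) && all(qk == rk)) return("=")
    if (nrow(q$exons) == 1L && nrow(r$exons) == 1L &&
        length(qpos) == length(rpos) && all(qpos == rpos)) return("=")
    if (all(qpos %in% rpos)) {
      sub <- length(qk) == 0L
      if (!sub && length(qk) <= length(rk)) {
        for (s0 in seq_len(length(rk) - length(qk) + 1L)) {
          if (all(qk == rk[s0:(s0 + length(qk) - 1L)])) { sub <- TRUE; break }
        }
      }
      if (sub) return("c")
    }
    if (length(intersect(qk, rk)) > 0L) return("j")
    if (nrow(q$exons) == 1L && exonic && length(rint_pos) > 0L &&
        any(qpos %in% rint_pos)) return("e")
    if (exonic) return("o")
    for (ip in rint_sets) if (all(qpos %in% ip)) return("i")
    if (!any(qpos %in% rspan)) {
      d_right <- min(qpos) - max(rpos) - 1L
      d_left <- min(rpos) - max(qpos) - 1L
      if ((d_right >= 0 && d_right <= runon) ||
          (d_left >= 0 && d_left <= runon)) return("p")
    }
    return(NA_character_)
  }
  if (exonic) return("x")
  if (any(qpos %in% rspan)) return("s")
  NA_character_
}

oracle_classify <- function(model, refs, runon = 2000) {
  order_codes <- c("=", "c", "j", "e", "o", "i", "x", "s", "p", "u")
  best <- "u"; best_ref <- ""
  ids <- vapply(refs, function(r) r$id, character(1))
  for (k in order(ids)) {
    code <- oracle_class_code(model, refs[[k]], runon)
    if (is.na(code)) next
    if (match(code, order_codes) < match(best, order_codes)) {
      best <- code; best_ref <- refs[[k]]$id
    }
  }
  list(code = best, reference_id = best_ref)
}

# hypergeometric upper tail by explicit combinatorial sum
oracle_hyper_tail <- function(k, K, N, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# duplex penalty by explicit per-position conditionals
oracle_duplex_score <- function(mirna, window) {
  m <- strsplit(mirna, "")[[1L]]
  w <- strsplit(window, "")[[1L]]
  L <- length(m)
  total <- 0
  for (i in seq_len(L)) {
    t <- w[L - i + 1L]
    pen <- if ((m[i] == "A" && t == "T") || (m[i] == "T" && t == "A") ||
               (m[i] == "G" && t == "C") || (m[i] == "C" && t == "G")) 0
           else if ((m[i] == "G" && t == "T") ||
                    (m[i] == "T" && t == "G")) 0.5
           else 1
    if (i >= 2 && i <= 13) pen <- pen * 2
    total <- total + pen
  }
  total
}

# exhaustive target-site oracle: score every window, then greedy
# best-score/leftmost non-overlapping selection
oracle_target_sites <- function(mirna, transcript, max_score = 3.0) {
  L <- nchar(mirna)
  starts <- seq_len(nchar(transcript) - L + 1L)
  sc <- vapply(starts, function(s)
    oracle_duplex_score(mirna, substr(transcript, s, s + L - 1L)),
    numeric(1))
  cand <- data.frame(start = starts - 1L, score = sc)[sc <= max_score, ]
  keep <- list()
  for (i in order(cand$score, cand$start)) {
    s <- cand$start[[i]]; e <- s + L - 1L
    clash <- any(vapply(keep, function(k)
      s <= k$e && k$s <= e, logical(1)))
    if (!clash) keep[[length(keep) + 1L]] <- list(s = s, e = e,
                                                  score = cand$score[[i]])
  }
  out <- do.call(rbind, lapply(keep, function(k)
    data.frame(start = k$s, score = k$score)))
  if (is.null(out)) return(data.frame(start = integer(0),
                                      score = numeric(0)))
  out[order(out$start), , drop = FALSE]
}

# exhaustive nested-structure enumeration (no memoization), n <= 15
oracle_max_pairs <- function(seq, min_loop = 3L) {
  s <- strsplit(toupper(seq), "")[[1L]]
  can <- function(x, y) {
    (x == "A" && y == "T") || (x == "T" && y == "A") ||
    (x == "G" && y == "C") || (x == "C" && y == "G") ||
    (x == "G" && y == "T") || (x == "T" && y == "G")
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i + 1L, j)
    for (k in seq(i + min_loop + 1L, j)) {
      if (can(s[i], s[k])) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    best
  }
  if (length(s) < 2L) return(0L)
  rec(1L, length(s))
}

# plain-R full Smith-Waterman DP (score only)
oracle_sw_score <- function(a, b, match = 1, mismatch = -2, gap = -2.5) {
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      H[i + 1L, j + 1L] <- max(
        0,
        H[i, j] + if (A[i] == B[j]) match else mismatch,
        H[i, j + 1L] + gap,
        H[i + 1L, j] + gap)
    }
  }
  max(H)
}

random_model <- function(id, chrom = "chr1", glen = 10000L,
                         max_exons = 3L) {
  n_ex <- sample.int(max_exons, 1L)
  # spacing >= 3 keeps exons and introns at length >= 1
  bounds <- sort(sample(seq(1L, glen - 1L, by = 3L), 2L * n_ex))
  ex <- matrix(bounds, ncol = 2, byrow = TRUE)
  ex[, 2L] <- ex[, 2L] + 1L  # half-open, length >= 1
  transcript_model(id, chrom, sample(c("+", "-"), 1L), ex)
}
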