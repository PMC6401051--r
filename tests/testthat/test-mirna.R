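mirna21 <- "GAGATTCGATCGGAGCTAGCT"  # fixed 21-nt test miRNA
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

test_that("score_duplex applies the penalty scheme with seed doubling", {
  w <- revcomp(mirna21)
  expect_equal(score_duplex(mirna21, w)$score, 0)
  L <- nchar(mirna21)
  mutate_at <- function(mir_pos, base) {
    # transcript partner of miRNA position i sits at window index L-i+1
    j <- L - mir_pos + 1L
    paste0(substr(w, 1, j - 1L), base, substr(w, j + 1L, L))
  }
  # mismatch at position 15 (outside 2-13): penalty 1
  m15 <- chars(mirna21)[15]
  bad15 <- setdiff(c("A", "C", "G", "T"),
                   c(chartr("ACGT", "TGCA", m15),
                     if (m15 == "G") "T", if (m15 == "T") "G"))[1]
  expect_equal(score_duplex(mirna21, mutate_at(15, bad15))$score, 1)
  # G:U at position 5 (inside 2-13): 0.5 doubled = 1
  expect_identical(chars(mirna21)[5], "T")
  expect_equal(score_duplex(mirna21, mutate_at(5, "G"))$score, 1)
  # boundary doubling: positions 2 and 13 doubled, 1 and 14 not
  for (pos in c(1, 2, 13, 14)) {
    m_i <- chars(mirna21)[pos]
    bad <- setdiff(c("A", "C", "G", "T"),
                   c(chartr("ACGT", "TGCA", m_i),
                     if (m_i == "G") "T", if (m_i == "T") "G"))[1]
    expect_equal(score_duplex(mirna21, mutate_at(pos, bad))$score,
                 if (pos %in% 2:13) 2 else 1, info = paste("pos", pos))
  }
  expect_error(score_duplex(mirna21, "ACGT"), "length")
})

test_that("score_duplex sees the same duplex from either strand", {
  set.seed(17)
  pen <- c(match = 0, GU = 0.5, mismatch = 1)
  for (i in 1:20) {
    m <- rand_dna(21)
    w <- rand_dna(21)
    a <- score_duplex(m, w)
    # the duplex read from the transcript strand's 5' end: roles swap
    # and positions reindex i -> L-i+1; per-position states reverse and
    # the unweighted penalty sum is preserved. (A literal reverse
    # complement of both strands is NOT an invariance: complementation
    # maps G:U pairs to C:A mismatches.)
    b <- score_duplex(w, m)
    expect_identical(rev(a$states), b$states)
    expect_equal(sum(pen[a$states]), sum(pen[b$states]))
  }
})

test_that("find_target_sites equals the exhaustive window oracle", {
  set.seed(18)
  for (i in 1:6) {
    tx <- rand_dna(sample(300:800, 1))
    m <- rand_dna(21)
    # plant one perfect site
    pos <- sample(50:200, 1)
    tx <- paste0(substr(tx, 1, pos - 1), revcomp(m),
                 substr(tx, pos + 21, nchar(tx)))
    got <- find_target_sites("mir", m, "tx", tx, max_score = 3)
    want <- oracle_target_sites(m, tx, max_score = 3)
    expect_identical(got$start, as.integer(want$start))
    expect_equal(got$score, want$score)
    expect_true((pos - 1) %in% got$start)
    expect_equal(got$score[got$start == pos - 1], 0)
  }
  # 4 seed mismatches (score 8) is not reported at max_score 3
  m <- mirna21
  w <- revcomp(m)
  L <- nchar(m)
  for (p in 3:6) {
    j <- L - p + 1
    m_i <- chars(m)[p]
    bad <- setdiff(c("A", "C", "G", "T"),
                   c(chartr("ACGT", "TGCA", m_i),
                     if (m_i == "G") "T", if (m_i == "T") "G"))[1]
    substr(w, j, j) <- bad
  }
  tx <- paste0(rand_dna(100), w, rand_dna(100))
  expect_false(any(find_target_sites("mir", m, "tx", tx)$start == 100))
})

test_that("eTM geometry: 3-nt bulge between positions 10/11 is required", {
  m <- mirna21
  etm_site <- paste0(revcomp(substr(m, 11, 21)), "CAA",
                     revcomp(substr(m, 1, 10)))
  tx <- paste0(rand_dna(60), etm_site, rand_dna(60))
  res <- find_etm_sites("mir", m, "tx", tx)
  expect_identical(nrow(res), 1L)
  expect_identical(res$start, 60L)
  expect_equal(res$pairing_ratio, 1.0)
  expect_identical(res$kind, "eTM")
  # same duplex without the bulge: a target, never an eTM
  tx2 <- paste0(rand_dna(60), revcomp(m), rand_dna(60))
  expect_identical(nrow(find_etm_sites("mir", m, "tx2", tx2)), 0L)
  t2 <- find_target_sites("mir", m, "tx2", tx2)
  expect_true(60 %in% t2$start)
  # flank mismatches are disqualifying
  weak <- etm_site
  for (j in c(2, 5, 8, 16, 20)) substr(weak, j, j) <- "N"
  tx3 <- paste0(rand_dna(60), weak, rand_dna(60))
  expect_identical(nrow(find_etm_sites("mir", m, "tx3", tx3)), 0L)
})

test_that("foldback fraction matches exhaustive structure enumeration", {
  # GGGAAACCC: 3 pairs -> fraction 6/9
  expect_identical(lncvine:::.nussinov_pairs("GGGAAACCC", 3L), 3L)
  expect_equal(foldback_fraction("GGGAAACCC"), 6 / 9)
  set.seed(19)
  for (i in 1:40) {
    s <- rand_dna(sample(6:15, 1))
    expect_identical(lncvine:::.nussinov_pairs(s, 3L),
                     oracle_max_pairs(s), info = s)
  }
})

test_that("find_precursors detects verbatim embeddings only", {
  set.seed(20)
  mat <- rand_dna(21)
  hp <- paste0(mat, rand_dna(8), revcomp(mat))
  lnc <- seq_set(c("host", "bystander"), c("host", "bystander"),
                 c(paste0(rand_dna(150), hp, rand_dna(150)),
                   rand_dna(350)))
  hps <- seq_set("hp1", "hp1", hp)
  res <- find_precursors(lnc, hps)
  expect_identical(res$lncRNA_id, "host")
  expect_equal(res$identity, 1)
  expect_equal(res$coverage, 1)
  # the two 21-nt arms can pair: fraction >= 2*21/50
  expect_gte(res$foldback_paired_fraction, 42 / 50)
  expect_error(find_precursors(lnc, hps[0, ]), "empty")
})

test_that("interaction roles and network assembly", {
  targets <- data.frame(mirna_id = "mir1",
                        transcript_id = c("l1", "l2"),
                        start = 0L, end = 21L, score = 0,
                        kind = "target")
  etms <- data.frame(mirna_id = "mir1", transcript_id = "l2",
                     start = 100L, end = 124L, bulge_start = 111L,
                     pairing_ratio = 1, kind = "eTM")
  precursors <- data.frame(hairpin_id = "mir1-hp", lncRNA_id = "l1",
                           start = 0L, end = 50L, identity = 1,
                           coverage = 1, foldback_paired_fraction = 0.8)
  cls <- classify_interactions(targets, etms, precursors)
  expect_identical(cls$roles$lncRNA_id, c("l1", "l2"))
  expect_true(all(cls$roles$target))
  expect_identical(cls$overlaps[["target_precursor"]], 1L)
  expect_identical(cls$overlaps[["target_eTM"]], 1L)
  expect_identical(cls$overlaps[["precursor_eTM"]], 0L)

  g <- build_network(targets = targets, etms = etms,
                     precursors = precursors)
  # star of mir1 (+ its hairpin node) and l1, l2
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 4)
  expect_setequal(unique(igraph::E(g)$kind),
                  c("target", "eTM", "precursor"))
  empty <- build_network()
  expect_equal(igraph::vcount(empty), 0)
  expect_error(
    build_network(targets = targets,
                  nodes = data.frame(id = "mir1", type = "miRNA")),
    "dangling")
  tmp <- withr::local_tempfile()
  paths <- export_network(g, tmp)
  expect_true(all(file.exists(paths)))
})

test_that("planted interactions recovered with no spurious eTMs over 20 seeds", {
  # scaled-down bundles keep this property check inside the time budget
  for (seed in 1:20) {
    b <- simulate_study(small_config(seed))
    man <- b$manifest
    cand <- b$transcripts[b$transcripts$id %in%
      man$transcripts$id[man$transcripts$type == "noncoding"], ]
    targets <- list(); etms <- list()
    for (i in seq_len(nrow(b$mirnas))) {
      for (j in seq_len(nrow(cand))) {
        targets[[length(targets) + 1L]] <- find_target_sites(
          b$mirnas$id[[i]], b$mirnas$seq[[i]], cand$id[[j]],
          cand$seq[[j]])
        etms[[length(etms) + 1L]] <- find_etm_sites(
          b$mirnas$id[[i]], b$mirnas$seq[[i]], cand$id[[j]],
          cand$seq[[j]])
      }
    }
    targets <- do.call(rbind, targets)
    etms <- do.call(rbind, etms)
    exp_t <- man$interactions[man$interactions$kind == "target", ]
    exp_e <- man$interactions[man$interactions$kind == "eTM", ]
    # recall 1.0 on planted sites
    expect_true(all(paste(exp_t$mirna_id, exp_t$lncRNA_id, exp_t$start) %in%
                    paste(targets$mirna_id, targets$transcript_id,
                          targets$start)), info = paste("seed", seed))
    # eTM calls are exactly the planted mimics: zero spurious
    expect_setequal(paste(etms$mirna_id, etms$transcript_id, etms$start),
                    paste(exp_e$mirna_id, exp_e$lncRNA_id, exp_e$start))
    prec <- find_precursors(cand, b$hairpins)
    exp_p <- man$interactions[man$interactions$kind == "precursor", ]
    expect_setequal(paste(prec$hairpin_id, prec$lncRNA_id),
                    paste(paste0(exp_p$mirna_id, "-hp"), exp_p$lncRNA_id))
  }
})
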