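cons_matrix <- function(rows) {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(names(rows), paste0("c", seq_len(ncol(m))))
  m
}

test_that("mean filter removal is strict below 30", {
  m <- cons_matrix(list(at30 = rep(30, 10), below = rep(29.9, 10),
                        above = rep(100, 10)))
  expect_setequal(mean_filter(m), c("at30", "above"))
})

test_that("pearson_edges matches the textbook formula and keeps signs", {
  set.seed(6)
  x <- rlnorm(10); y <- 3 * x + 1  # r = 1
  m <- cons_matrix(list(l1 = x, p1 = y, anti = max(x) + 1 - x,
                        noise = rlnorm(10)))
  e <- pearson_edges("l1", c("p1", "anti", "noise"), m)
  expect_setequal(e$partner_id, c("p1", "anti"))
  expect_equal(e$r[e$partner_id == "p1"], 1, tolerance = 1e-12)
  expect_equal(e$r[e$partner_id == "anti"], -1, tolerance = 1e-12)
  expect_identical(e$sign[e$partner_id == "anti"], "-")
  # closed-form check to 1e-12 on random vectors
  for (i in 1:20) {
    a <- rlnorm(10); b <- rlnorm(10)
    manual <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    mm <- cons_matrix(list(a = a, b = b))
    got <- pearson_edges("a", "b", mm, r2_threshold = 0)
    expect_equal(got$r, manual, tolerance = 1e-12)
  }
  # zero-variance profiles yield no edges
  mz <- cons_matrix(list(flat = rep(5, 10), v = rlnorm(10)))
  expect_identical(nrow(pearson_edges("flat", "v", mz)), 0L)
  expect_error(pearson_edges("a", "b", cons_matrix(list(a = 1:2, b = 2:1))),
               "3 conditions")
})

test_that("random unrelated profiles rarely form edges", {
  set.seed(13)
  rows <- lapply(1:40, function(i) rlnorm(10))
  names(rows) <- paste0("t", 1:40)
  m <- cons_matrix(rows)
  e <- pearson_edges(paste0("t", 1:20), paste0("t", 21:40), m)
  expect_lt(nrow(e) / 400, 0.05)
})

test_that("bootstrap support is deterministic and favors clean pairs", {
  set.seed(10)
  x <- rlnorm(10)
  s1 <- bootstrap_support(x, 2 * x, seed = 99)
  s2 <- bootstrap_support(x, 2 * x, seed = 99)
  expect_identical(s1, s2)
  expect_equal(s1, 1.0)
  noisy <- vapply(1:10, function(i)
    bootstrap_support(x, x * rlnorm(10, 0, 0.6), seed = i), numeric(1))
  expect_gt(s1, mean(noisy))
})

test_that("annotation transfer unions partner terms with witnesses", {
  edges <- data.frame(lncRNA_id = c("l1", "l1", "l2"),
                      partner_id = c("m1", "m2", "m1"),
                      partner_kind = "mRNA")
  tt <- data.frame(transcript_id = c("m1", "m2", "m2"),
                   term = c("GO:0015979", "GO:0015979", "GO:0006412"),
                   label = c("photosynthesis", "photosynthesis",
                             "translation"))
  res <- transfer_annotations(edges, tt)
  l1 <- res[res$lncRNA_id == "l1", ]
  expect_setequal(l1$term, c("GO:0015979", "GO:0006412"))
  expect_identical(l1$witnesses[l1$term == "GO:0015979"], "m1,m2")
  expect_identical(res$term[res$lncRNA_id == "l2"], "GO:0015979")
  none <- transfer_annotations(edges[0, ], tt)
  expect_identical(nrow(none), 0L)
})

test_that("enrichment equals the exhaustive tail-sum oracle", {
  set.seed(12)
  for (i in 1:25) {
    N <- sample(10:50, 1L)
    bg <- paste0("g", seq_len(N))
    n <- sample(3:N, 1L)
    sel <- sample(bg, n)
    tt <- data.frame(transcript_id = sample(bg, sample(5:N, 1L)),
                     term = "GO:0000001", label = "t")
    res <- enrichment(sel, tt, bg)
    K <- length(unique(tt$transcript_id))
    k <- length(intersect(unique(tt$transcript_id), sel))
    expect_equal(res$p, oracle_hyper_tail(k, K, N, n), tolerance = 1e-12)
  }
  # term in all selected and all background: p = 1
  bg <- paste0("g", 1:20)
  tt_all <- data.frame(transcript_id = bg, term = "GO:0000002",
                       label = "x")
  expect_equal(enrichment(bg[1:5], tt_all, bg)$p, 1)
  expect_identical(nrow(enrichment(character(0), tt_all, bg)), 0L)
  expect_error(enrichment("zzz", tt_all, bg), "subset")
})

test_that("local aligner equals the full DP oracle on short pairs", {
  set.seed(14)
  for (i in 1:30) {
    a <- rand_dna(sample(5:50, 1L))
    b <- rand_dna(sample(5:50, 1L))
    got <- local_align(a, b)
    expect_equal(got$score, oracle_sw_score(a, b), info = paste(a, b))
  }
  # a planted exact shared segment is found with identity 1
  core <- rand_dna(30)
  al <- local_align(paste0(rand_dna(10), core, rand_dna(10)),
                    paste0(rand_dna(5), core, rand_dna(15)))
  expect_gte(al$score, 30)
  expect_equal(al$identity, 1)
})

test_that("organelle homology is strict above 200 nt", {
  hits <- data.frame(query_id = c("l1", "l2"), subject_id = c("o1", "o2"),
                     percent_identity = c(99, 98),
                     align_length = c(200, 201), mismatches = 0,
                     gap_opens = 0, q_start = 1, q_end = 200, s_start = 1,
                     s_end = 200, evalue = 0, bit_score = 400)
  res <- organelle_homology(NULL, hits = hits)
  expect_identical(res$lncRNA_id, "l2")  # 200 discarded, 201 kept
  # internal aligner finds a planted 300-nt shared segment
  seg <- rand_dna(300)
  lnc <- seq_set("l1", "l1", paste0(rand_dna(100), seg, rand_dna(100)))
  org <- seq_set("o1", "o1", paste0(rand_dna(50), seg, rand_dna(50)))
  found <- organelle_homology(lnc, org)
  expect_identical(found$lncRNA_id, "l1")
  expect_gte(found$align_length, 300)
})
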