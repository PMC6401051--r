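mk_hit <- function(q, s, ident, ev, bits, ss, se) {
  data.frame(query_id = q, subject_id = s, percent_identity = ident,
             align_length = abs(se - ss) + 1L, mismatches = 0L,
             gap_opens = 0L, q_start = 1L, q_end = abs(se - ss) + 1L,
             s_start = ss, s_end = se, evalue = ev, bit_score = bits,
             stringsAsFactors = FALSE)
}

test_that("assign_chromosome applies strict thresholds and tie rules", {
  h <- mk_hit("t1", "chr1", 95, 1e-20, 200, 100, 399)
  res <- assign_chromosome(h)
  expect_identical(res$placed$transcript_id, "t1")
  expect_identical(res$placed$strand, "+")
  expect_equal(c(res$placed$start, res$placed$end), c(99, 399))

  # identity exactly 90 fails (strict >)
  res90 <- assign_chromosome(mk_hit("t1", "chr1", 90, 1e-20, 200, 1, 100))
  expect_identical(res90$unplaced, "t1")

  # best hit by bit score; minus orientation from coordinates
  two <- rbind(mk_hit("t1", "chr1", 95, 1e-20, 180, 1, 100),
               mk_hit("t1", "chr2", 95, 1e-30, 200, 500, 300))
  best <- assign_chromosome(two)
  expect_identical(best$placed$chrom, "chr2")
  expect_identical(best$placed$strand, "-")
  expect_equal(c(best$placed$start, best$placed$end), c(299, 500))
})

test_that("density and share match a naive recount", {
  set.seed(5)
  lens <- c(chr1 = 2e6, chr2 = 1e6, chr3 = 5e5)
  loci <- data.frame(chrom = sample(names(lens), 300, replace = TRUE,
                                    prob = c(0.5, 0.3, 0.2)))
  tab <- density_and_distribution(loci, lens)
  expect_equal(sum(tab$share), 100, tolerance = 1e-9)
  for (ch in names(lens)) {
    cnt <- sum(loci$chrom == ch)
    expect_identical(tab$count[tab$chrom == ch], cnt)
    expect_equal(tab$density[tab$chrom == ch], cnt / (lens[[ch]] / 1e6))
  }
  # 100 transcripts on a 2 Mbp chromosome = 50 per Mbp
  t2 <- density_and_distribution(
    data.frame(chrom = rep("c", 100)), c(c = 2e6))
  expect_equal(t2$density, 50)
  expect_equal(t2$share, 100)
  expect_error(density_and_distribution(data.frame(chrom = "nope"), lens),
               "unknown chromosome")
})

test_that("length histogram uses left-open right-closed bins", {
  counts <- length_histogram(c(300, 400), bin_edges = c(250, 500))
  expect_identical(unname(counts), c(0L, 2L, 0L))
  expect_identical(sum(length_histogram(numeric(0))), 0L)
  set.seed(9)
  lens <- sample(1:5000, 1000, replace = TRUE)
  edges <- c(250, 500, 1000, 2000, 4000)
  counts <- length_histogram(lens, edges)
  brute <- c(sum(lens <= 250),
             sum(lens > 250 & lens <= 500), sum(lens > 500 & lens <= 1000),
             sum(lens > 1000 & lens <= 2000),
             sum(lens > 2000 & lens <= 4000), sum(lens > 4000))
  expect_identical(unname(counts), as.integer(brute))
})

test_that("classify_transcript reproduces the documented examples", {
  ref <- transcript_model("r1", "chr1", "+",
                          rbind(c(999, 2000), c(3999, 5000)))
  refs <- list(r1 = ref)
  # single exon fully inside the intron, same strand -> 'i'
  q_i <- transcript_model("q1", "chr1", "+", rbind(c(2499, 2800)))
  expect_identical(classify_transcript(q_i, refs)$code, "i")
  # opposite strand overlapping an exon -> 'x'
  q_x <- transcript_model("q2", "chr1", "-", rbind(c(1199, 1800)))
  expect_identical(classify_transcript(q_x, refs)$code, "x")
  # identical coordinates, same strand, single exon references
  ref1 <- list(r = transcript_model("r", "chr1", "+", rbind(c(10, 400))))
  q_eq <- transcript_model("q", "chr1", "+", rbind(c(10, 400)))
  expect_identical(classify_transcript(q_eq, ref1)$code, "=")
  # identical intron chain (multi-exon) -> '='
  q_eq2 <- transcript_model("q", "chr1", "+",
                            rbind(c(1499, 2000), c(3999, 4500)))
  expect_identical(classify_transcript(q_eq2, refs)$code, "=")
  # shares the intron but adds a second one -> 'j'
  q_j <- transcript_model("q", "chr1", "+",
                          rbind(c(1499, 2000), c(3999, 4200),
                                c(4299, 4500)))
  expect_identical(classify_transcript(q_j, refs)$code, "j")
  # run-on fragment within 2 kb downstream of the 3' end
  q_p <- transcript_model("q", "chr1", "+", rbind(c(6000, 6400)))
  expect_identical(classify_transcript(q_p, refs)$code, "p")
  # far away -> 'u', no witness
  q_u <- transcript_model("q", "chr1", "+", rbind(c(20000, 20500)))
  res_u <- classify_transcript(q_u, refs)
  expect_identical(res_u$code, "u")
  expect_identical(res_u$reference_id, "")
  # unknown chromosome -> 'u'
  q_c <- transcript_model("q", "chrZ", "+", rbind(c(1000, 1500)))
  expect_identical(classify_transcript(q_c, refs)$code, "u")
})

test_that("classification matches the enumeration oracle with strand symmetry", {
  set.seed(21)
  flip <- function(m) transcript_model(
    m$id, m$chrom, if (m$strand == "+") "-" else "+", m$exons)
  for (i in 1:120) {
    refs <- lapply(seq_len(sample(1:2, 1L)), function(k)
      random_model(paste0("r", k), glen = 4000L))
    names(refs) <- vapply(refs, function(r) r$id, character(1))
    q <- random_model("q", glen = 4000L, max_exons = 2L)
    got <- classify_transcript(q, refs)
    want <- oracle_classify(q, refs)
    expect_identical(got$code, want$code,
                     info = paste("case", i))
    expect_identical(got$reference_id, want$reference_id)
    # relabeling both strands leaves the code unchanged
    got_f <- classify_transcript(flip(q), lapply(refs, flip))
    expect_identical(got_f$code, got$code)
  }
})

test_that("class-code summary percentages sum to 100", {
  res <- data.frame(transcript_id = letters[1:4],
                    code = c("u", "u", "i", "x"),
                    reference_id = c("", "", "r", "r"))
  s <- class_code_summary(res)
  expect_equal(sum(s$percent), 100)
  expect_identical(s$count[s$code == "u"], 2L)
  all_u <- class_code_summary(data.frame(transcript_id = "a", code = "u",
                                         reference_id = ""))
  expect_equal(all_u$percent, 100)
  expect_identical(nrow(class_code_summary(res[0, ])), 0L)
})
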