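test_that("scan_orfs finds the canonical minimal ORF in both orientations", {
  orfs <- scan_orfs("ATGAAATAA")
  expect_identical(nrow(orfs), 1L)
  expect_identical(orfs$frame, "+1")
  expect_identical(orfs$aa_length, 2L)
  expect_true(orfs$complete)
  expect_equal(c(orfs$start, orfs$end), c(0, 9))

  rc <- revcomp("ATGAAATAA")
  orfs_rc <- scan_orfs(rc)
  expect_identical(orfs_rc$frame, "-1")
  expect_identical(orfs_rc$aa_length, 2L)
})

test_that("scan_orfs handles N codons and truncation", {
  # N breaks the ATG match but not elsewhere
  expect_identical(nrow(scan_orfs("ATNAAATAA")), 0L)
  # ATG with no stop: incomplete, runs to the sequence end
  orfs <- scan_orfs("ATGAAAAAA")
  plus1 <- orfs[orfs$frame == "+1", ]
  expect_false(plus1$complete)
  expect_identical(plus1$aa_length, 3L)
  # N in a later codon is not a stop: ORF runs through it
  orfs2 <- scan_orfs("ATGANATAA")
  plus2 <- orfs2[orfs2$frame == "+1", ]
  expect_identical(plus2$aa_length, 2L)
  expect_true(plus2$complete)
})

test_that("scan_orfs matches the exhaustive codon-walk oracle", {
  set.seed(11)
  for (i in 1:60) {
    s <- rand_dna(sample(10:600, 1L))
    expect_identical(max_orf_aa(s), oracle_max_orf_aa(s), info = s)
  }
})

test_that("length filter is strict at 200 nt and keeps the 224-nt case", {
  recs <- seq_set(c("a", "b", "c"), c("a", "b", "c"),
                  vapply(c(200L, 224L, 201L), rand_dna, character(1)))
  part <- filter_by_length(recs)
  expect_identical(part$removed$id, "a")
  expect_setequal(part$kept$id, c("b", "c"))
  expect_identical(nrow(filter_by_length(recs[0, ])$kept), 0L)
})

test_that("ORF filter boundary: 100 aa kept, 101 aa removed", {
  orf_seq <- function(codons) {
    paste0("ATG",
           paste(rep("GCT", codons - 1L), collapse = ""), "TAA")
  }
  recs <- seq_set(c("aa100", "aa101"), c("aa100", "aa101"),
                  c(orf_seq(100L), orf_seq(101L)))
  part <- filter_by_orf(recs)
  expect_identical(part$kept$id, "aa100")
  expect_identical(part$removed$id, "aa101")
  # truncated ORFs count by default but not with require_complete
  trunc <- seq_set("t", "t",
                   paste0("ATG", paste(rep("GCT", 150), collapse = "")))
  expect_identical(nrow(filter_by_orf(trunc)$removed), 1L)
  expect_identical(nrow(filter_by_orf(trunc, require_complete = TRUE)$removed),
                   0L)
})

test_that("score filter keeps strictly negative scores, warns on missing", {
  recs <- seq_set(c("a", "b", "c"), c("a", "b", "c"),
                  c(rand_dna(50), rand_dna(50), rand_dna(50)))
  part <- apply_score_filter(recs, c(a = -1.2, b = 0.0, c = 2))
  expect_identical(part$kept$id, "a")
  expect_setequal(part$removed$id, c("b", "c"))
  expect_warning(part2 <- apply_score_filter(recs, c(a = -1)), "missing")
  expect_setequal(part2$kept$id, c("a", "b", "c"))
})

test_that("homology filter removes any transcript with a hit", {
  recs <- seq_set(c("a", "b"), c("a", "b"), c(rand_dna(50), rand_dna(50)))
  hits <- data.frame(query_id = c("a", "a", "a"))
  part <- apply_homology_filter(recs, hits)
  expect_identical(part$removed$id, "a")
  expect_identical(part$kept$id, "b")
})

test_that("funnel telescopes, recovers the manifest, and is order-invariant", {
  b <- default_bundle()
  ident <- run_identification(b$transcripts, score_table = b$score_table,
                              hit_table = b$protein_hits)
  rep <- ident$report
  expect_identical(rep$stage,
                   c("length", "orf", "coding_score", "homology"))
  expect_identical(rep$input - rep$removed, rep$retained)
  expect_identical(rep$retained[-nrow(rep)], rep$input[-1L])
  expect_true(all(diff(rep$retained) <= 0))

  noncoding <- b$manifest$transcripts$id[
    b$manifest$transcripts$type == "noncoding"]
  expect_setequal(ident$candidates$id, noncoding)

  # filters are independent predicates: applying them in reverse order
  # yields the same final set
  alt <- apply_homology_filter(b$transcripts, b$protein_hits)$kept
  alt <- apply_score_filter(alt, b$score_table)$kept
  alt <- filter_by_orf(alt)$kept
  alt <- filter_by_length(alt)$kept
  expect_setequal(alt$id, ident$candidates$id)

  # no optional tables: two-stage report; empty input: all-zero report
  expect_identical(nrow(run_identification(b$transcripts)$report), 2L)
  empty <- run_identification(b$transcripts[0, ])
  expect_true(all(empty$report$input == 0L))
})
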