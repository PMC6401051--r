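mk_samples <- function(n_cond, n_rep) {
  conds <- paste0("c", seq_len(n_cond))
  data.frame(sample = paste0(rep(conds, each = n_rep), "_R",
                             seq_len(n_rep)),
             tissue = rep(conds, each = n_rep), stage = "s",
             replicate = seq_len(n_rep),
             condition = rep(conds, each = n_rep),
             stringsAsFactors = FALSE)
}

test_that("consensus expression is the replicate mean", {
  samples <- mk_samples(2, 2)
  m <- matrix(c(10, 20, 5, 5, 1, 3, 0, 8), nrow = 2, byrow = TRUE,
              dimnames = list(c("t1", "t2"), samples$sample))
  cons <- consensus_expression(m, samples)
  expect_equal(cons["t1", "c1"], 15)
  expect_equal(unname(cons["t2", ]), c(2, 4))
  # random matrix equals a naive recompute
  set.seed(3)
  samples10 <- mk_samples(10, 3)
  mm <- matrix(rlnorm(50 * 30), nrow = 50,
               dimnames = list(paste0("t", 1:50), samples10$sample))
  cons10 <- consensus_expression(mm, samples10)
  for (cc in unique(samples10$condition)) {
    expect_equal(cons10[, cc],
                 rowMeans(mm[, samples10$sample[samples10$condition == cc]]))
  }
  # median flag
  m3 <- matrix(c(1, 2, 100), nrow = 1,
               dimnames = list("t", paste0("c1_R", 1:3)))
  s3 <- mk_samples(1, 3)
  expect_equal(unname(consensus_expression(m3, s3, fun = "median")[1, 1]),
               2)
})

test_that("bh_adjust matches hand computation and p.adjust", {
  expect_equal(bh_adjust(0.01), 0.01)
  # ranked (0.01,0.02,0.03,0.04): m*p/i = 0.04 everywhere
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(8)
  p <- runif(200)
  expect_equal(bh_adjust(p), p.adjust(p, method = "BH"))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_identical(length(bh_adjust(numeric(0))), 0L)
})

test_that("expression bins reproduce the printed boundaries", {
  vals <- c(0, 3, 5, 5.0001, 10, 20, 20.5, 50, 70, 100, 300, 500, 800,
            1000, 1000.01)
  want <- c("not expressed", "extremely low", "extremely low", "very low",
            "very low", "very low", "low", "low", "moderate", "moderate",
            "high", "high", "very high", "very high", "extremely high")
  expect_identical(as.character(bin_expression(vals)), want)
  expect_error(bin_expression(-1), "negative")
})

test_that("specificity index closed forms and scale invariance", {
  one_hot <- setNames(c(0, 0, 12, 0), paste0("c", 1:4))
  res <- specificity_index(one_hot)
  expect_equal(res$max_index, 1)
  expect_true(res$is_specific)
  expect_identical(res$condition, "c3")

  unif <- setNames(rep(7, 10), paste0("c", 1:10))
  res_u <- specificity_index(unif)
  expect_equal(res_u$max_index, 0.1, tolerance = 1e-12)
  expect_false(res_u$is_specific)

  row31 <- setNames(c(3, 1), c("a", "b"))
  res31 <- specificity_index(row31)
  expect_equal(unname(res31$indices), c(0.75, 0.25))
  expect_true(res31$is_specific)

  set.seed(2)
  r <- setNames(rlnorm(10), paste0("c", 1:10))
  expect_equal(specificity_index(r)$indices,
               specificity_index(r * 17.3)$indices)
  expect_equal(sum(specificity_index(r)$indices), 1)

  zero <- setNames(rep(0, 5), paste0("c", 1:5))
  res0 <- specificity_index(zero)
  expect_true(res0$all_zero)
  expect_false(res0$is_specific)
  expect_error(specificity_index(c(a = -1, b = 2)), "negative")
  expect_error(specificity_index(c(a = 1)), "two conditions")
})

test_that("plant_specific_profile round-trips through the index", {
  base <- setNames(rep(10, 10), paste0("c", 1:10))
  row <- plant_specific_profile(base, "c4", 0.8)
  expect_equal(sum(row), sum(base))
  res <- specificity_index(row)
  expect_equal(res$max_index, 0.8, tolerance = 1e-9)
  expect_identical(res$condition, "c4")
  # one-hot at index 1
  row1 <- plant_specific_profile(base, "c1", 1.0)
  expect_equal(unname(row1), c(100, rep(0, 9)))
  expect_error(plant_specific_profile(base, "c1", 0.1), "exceed")
})

test_that("de_filter flags planted folds and respects thresholds", {
  set.seed(4)
  samples <- mk_samples(3, 3)
  cons <- rbind(t8 = c(80, 10, 10), t2 = c(20, 10, 10),
                flat = c(10, 10, 10))
  noise <- matrix(rlnorm(3 * 9, -0.001, 0.02), nrow = 3)
  m <- cons[, rep(1:3, each = 3)] * noise
  colnames(m) <- samples$sample
  de <- de_filter(m, samples)
  expect_true("t8" %in% de$de_transcripts)
  expect_false("t2" %in% de$de_transcripts)  # 2-fold < 4-fold
  expect_false("flat" %in% de$de_transcripts)
  res <- de$results
  expect_true(all(res$is_de ==
                  (abs(res$log2fc) >= 2 & res$fdr <= 0.001)))
  # <2 replicates and no ingested p-values is an error
  s1 <- mk_samples(3, 1)
  m1 <- cons
  colnames(m1) <- s1$sample
  expect_error(de_filter(m1, s1), "replicates")
  # ingested p-value table takes over
  ptab <- expand.grid(transcript_id = rownames(cons),
                      comparison = c("c1|c2", "c1|c3", "c2|c3"),
                      stringsAsFactors = FALSE)
  ptab$p_value <- ifelse(ptab$transcript_id == "t8", 1e-8, 0.9)
  de1 <- de_filter(m1, s1, p_table = ptab)
  expect_identical(de1$de_transcripts, "t8")
})
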