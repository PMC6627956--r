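test_that("pairwise identity reproduces hand-checked cases", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"), 1.0)
  # 3 matches over 4 columns in every optimal alignment
  expect_equal(pairwise_identity("ACGT", "AGGT"), 0.75)
  # no matches in any optimal alignment
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0.0)
})

test_that("pairwise identity is symmetric", {
  set.seed(61)
  for (i in 1:20) {
    a <- random_dna(sample(20:120, 1))
    b <- if (i %% 2) random_dna(sample(20:120, 1)) else
      mutate_sequence(a, error_model())
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("alignment scores agree with a pure-R Gotoh oracle", {
  set.seed(67)
  for (i in 1:25) {
    a <- random_dna(sample(5:60, 1))
    b <- if (i %% 2) random_dna(sample(5:60, 1)) else
      mutate_sequence(a, error_model(0.1, 0.05, 0.08))
    got <- barcodetrack:::nw_align_cpp(a, b, 1, -1, -2, -1, 0L)$score
    expect_equal(got, r_gotoh_score(a, b))
  }
})

test_that("alignment scores agree with Biostrings pairwiseAlignment", {
  set.seed(71)
  for (i in 1:30) {
    a <- random_dna(sample(50:300, 1))
    b <- if (i %% 3 == 0) random_dna(sample(50:300, 1)) else
      mutate_sequence(a, error_model())
    got <- barcodetrack:::nw_align_cpp(a, b, 1, -1, -2, -1, 0L)$score
    expect_equal(got, biostrings_score(a, b))
  }
})

test_that("greedy clustering separates target and contaminant reads", {
  sim <- make_sim_sample(n_reads = 100, seed = 17, contam_frac = 0.2)
  core <- preprocess_sim(sim)
  cl <- greedy_cluster(core, t = 0.70)
  sizes <- vapply(cl, `[[`, integer(1), "abundance")
  expect_equal(length(cl), 2)
  # retained ~80/20 split up to demux/length-filter losses
  origin <- core$origin
  expect_equal(sort(sizes, decreasing = TRUE),
               sort(as.integer(table(origin)), decreasing = TRUE))
  dom <- select_dominant(cl)
  dom_origin <- origin[dom$member_idx]
  expect_gte(mean(dom_origin == "target"), 0.99)
})

test_that("degenerate clustering cases behave as specified", {
  one <- seq_records("a", random_dna(100))
  cl1 <- greedy_cluster(one)
  expect_equal(length(cl1), 1)
  expect_equal(cl1[[1]]$abundance, 1)

  same <- seq_records(sprintf("r%d", 1:6), rep(random_dna(150), 6))
  cl2 <- greedy_cluster(same)
  expect_equal(length(cl2), 1)
  expect_equal(cl2[[1]]$abundance, 6)
})

test_that("clusters partition the input reads", {
  sim <- make_sim_sample(n_reads = 80, seed = 53, contam_frac = 0.3)
  core <- preprocess_sim(sim)
  cl <- greedy_cluster(core)
  all_idx <- sort(unlist(lapply(cl, `[[`, "member_idx")))
  expect_identical(all_idx, seq_len(nrow(core)))
  for (c in cl) {
    for (m in c$member_idx[seq_len(min(3, length(c$member_idx)))]) {
      expect_gte(pairwise_identity(core$seq[m], c$centroid_seq, band = 150),
                 0.70)
    }
  }
})

test_that("dominant-cluster selection breaks ties toward the earlier centroid", {
  set.seed(83)
  a <- random_dna(120)
  b <- random_dna(120)  # unrelated: identity << 0.7
  reads <- seq_records(sprintf("r%d", 1:4), c(a, b, a, b))
  cl <- greedy_cluster(reads)
  sizes <- vapply(cl, `[[`, integer(1), "abundance")
  expect_equal(sizes, c(2L, 2L))
  expect_equal(select_dominant(cl)$centroid_id, "r1")
})

test_that("dominant-cluster retention stays in the paper-like band", {
  sim <- make_sim_sample(n_reads = 400, seed = 59)  # default contamination
  core <- preprocess_sim(sim)
  cl <- greedy_cluster(core)
  retention <- select_dominant(cl)$abundance / nrow(core)
  expect_gte(retention, 0.7)
  expect_lte(retention, 1.0)
})

test_that("the 8-mer prefilter only skips pairs that fail the threshold", {
  set.seed(89)
  for (i in 1:40) {
    a <- random_dna(300)
    b <- switch(i %% 4 + 1,
                random_dna(300),
                mutate_sequence(a, error_model()),
                barcodetrack:::diverge_reference(a, 0.3),
                barcodetrack:::diverge_reference(a, 0.45))
    shared <- sum(barcodetrack:::kmer_set(a) %in% barcodetrack:::kmer_set(b))
    if (shared < 3)
      expect_lt(pairwise_identity(a, b), 0.70)
  }
  # and the prefilter does not change clustering results
  sim <- make_sim_sample(n_reads = 60, seed = 97, contam_frac = 0.25)
  core <- preprocess_sim(sim)
  cl_on <- greedy_cluster(core, prefilter = TRUE)
  cl_off <- greedy_cluster(core, prefilter = FALSE)
  expect_identical(lapply(cl_on, `[[`, "member_ids"),
                   lapply(cl_off, `[[`, "member_ids"))
})
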