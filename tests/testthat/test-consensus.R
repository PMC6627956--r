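test_that("subsampling is seeded, deterministic and size-capped", {
  set.seed(3)
  reads <- seq_records(sprintf("r%04d", 1:1000),
                       vapply(rep(40, 1000), random_dna, character(1)))
  s1 <- subsample_reads(reads, 200, seed = 1)
  s1b <- subsample_reads(reads, 200, seed = 1)
  s3 <- subsample_reads(reads, 200, seed = 3)
  expect_equal(nrow(s1), 200)
  expect_identical(s1$id, s1b$id)
  # different seeds pick different read sets (hypergeometric: the expected
  # overlap of two independent 200-of-1000 draws is 40, never all 200)
  expect_lt(length(intersect(s1$id, s3$id)), 200)

  small <- reads[1:150, ]
  expect_warning(sall <- subsample_reads(small, 200, seed = 1), "150")
  expect_equal(nrow(sall), 150)
})

test_that("partial-order MSA reproduces small hand-checked alignments", {
  m1 <- build_msa(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(m1$n_columns, 8)
  expect_false(any(grepl("-", m1$rows, fixed = TRUE)))

  m2 <- build_msa(c(a = "ACGT", b = "ACGGT"))
  expect_equal(m2$n_columns, 5)
  expect_equal(sum(strsplit(m2$rows[1], "")[[1]] == "-"), 1)
  expect_false(grepl("-", m2$rows[2], fixed = TRUE))
})

test_that("gap removal from any MSA row reproduces the read exactly", {
  set.seed(107)
  tmpl <- make_reference(300, seed = 6)
  reads <- vapply(1:30, function(i) mutate_sequence(tmpl, error_model()),
                  character(1))
  msa <- build_msa(seq_records(sprintf("r%d", 1:30), reads))
  expect_identical(gsub("-", "", msa$rows, fixed = TRUE), reads)
  expect_equal(length(unique(nchar(msa$rows))), 1)
})

test_that("draft length stays within 2% of the template length", {
  sim <- make_sim_sample(n_reads = 260, seed = 37, contam_frac = 0)
  core <- preprocess_sim(sim)
  sub <- subsample_reads(core, 200, seed = 1)
  draft <- plurality_consensus(build_msa(sub))
  expect_lt(abs(nchar(draft) - nchar(sim$truth_core)),
            0.02 * nchar(sim$truth_core))
})

test_that("the plurality threshold is the exact real-valued product", {
  expect_equal(plurality_threshold(200, 0.15), 30)
  for (n in c(10, 50, 137, 200, 333))
    expect_equal(plurality_threshold(n, 0.15) / n, 0.15)
})

test_that("column calls follow the plurality and gap-majority rules", {
  # 10 rows: a unanimous column, a sub-threshold column and a gap-majority
  # column (6 gaps of 10)
  rows <- c(rep("GA-", 6), "GAT", "GCT", "GGT", "GTT")
  msa <- structure(list(row_ids = sprintf("r%d", 1:10), rows = rows,
                        n_columns = 3), class = "barcode_msa")
  # p = 0.5: threshold 5; col1 G kept; col2: A has 7 >= 5; col3 dropped (gap
  # majority)
  expect_equal(plurality_consensus(msa, p = 0.5), "GA")
  # p = 0.15 on a split column keeps the alphabetically-first tied winner
  rows2 <- c("A", "A", "C", "C", "G", "T")
  msa2 <- structure(list(row_ids = sprintf("r%d", 1:6), rows = rows2,
                         n_columns = 1), class = "barcode_msa")
  expect_equal(plurality_consensus(msa2, p = 0.15), "A")
})

test_that("sub-threshold columns become N and are stripped", {
  # 7 rows, p = 0.5 -> threshold 3.5; middle column max count 2 < 3.5 -> N
  rows <- c("AAT", "AAT", "ACT", "ACT", "AGT", "AGT", "ATT")
  msa <- structure(list(row_ids = sprintf("r%d", 1:7), rows = rows,
                        n_columns = 3), class = "barcode_msa")
  out <- plurality_consensus(msa, p = 0.5)
  expect_equal(out, "AT")
  expect_false(grepl("[N-]", out))
})

test_that("error-free reads reproduce the template exactly", {
  tmpl <- make_reference(400, list(c("A", 7, 100)), seed = 10)
  reads <- seq_records(sprintf("r%d", 1:50), rep(tmpl, 50))
  draft <- plurality_consensus(build_msa(reads))
  expect_identical(draft, tmpl)
})

test_that("raising the plurality fraction only shortens the draft", {
  sim <- make_sim_sample(n_reads = 120, seed = 113, contam_frac = 0)
  core <- preprocess_sim(sim)
  msa <- build_msa(subsample_reads(core, 100, seed = 1))
  is_subseq <- function(s, t) {
    # is s a subsequence of t?
    sc <- strsplit(s, "")[[1]]; tc <- strsplit(t, "")[[1]]
    i <- 1
    for (ch in tc) {
      if (i <= length(sc) && sc[i] == ch) i <- i + 1
    }
    i > length(sc)
  }
  drafts <- vapply(c(0.15, 0.25, 0.35, 0.5), function(p)
    plurality_consensus(msa, p), character(1))
  expect_false(any(grepl("[N-]", drafts)))
  for (k in 2:length(drafts)) {
    expect_lte(nchar(drafts[k]), nchar(drafts[k - 1]))
    expect_true(is_subseq(drafts[k], drafts[k - 1]))
  }
})
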