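test_that("draft alignment reproduces hand-checked CIGARs", {
  set.seed(127)
  draft <- random_dna(200)
  al <- align_to_draft(draft, draft)
  expect_equal(al$cigar, "200M")
  expect_equal(al$identity, 1.0)

  read_del <- paste0(substr(draft, 1, 99), substr(draft, 101, 200))
  al2 <- align_to_draft(read_del, draft)
  expect_equal(sum(strsplit(al2$aligned_read, "")[[1]] == "-"), 1)
  expect_match(al2$cigar, "^[0-9]+M1D[0-9]+M$")

  expect_null(align_to_draft(substr(draft, 1, 80), draft))  # < half: unmappable
})

test_that("banded and unbanded alignment give identical scores", {
  set.seed(131)
  tmpl <- make_reference(300, seed = 12)
  for (i in 1:100) {
    read <- mutate_sequence(tmpl, error_model())
    banded <- align_to_draft(read, tmpl)$score
    full <- barcodetrack:::nw_align_cpp(read, tmpl, 1, -1, -2, -1, 0L)$score
    expect_equal(banded, full)
  }
})

test_that("polishing error-free reads is a fixed point", {
  tmpl <- make_reference(400, list(c("C", 8, 200)), seed = 14)
  reads <- seq_records(sprintf("r%d", 1:60), rep(tmpl, 60))
  expect_identical(polish_consensus(tmpl, reads, n = 50, seed = 2), tmpl)
})

test_that("a planted draft error is corrected by the pileup majority", {
  tmpl <- make_reference(400, seed = 15)
  flip <- c(A = "C", C = "G", G = "T", T = "A")
  draft <- tmpl
  substr(draft, 157, 157) <- flip[[substr(tmpl, 157, 157)]]
  corrected <- 0L
  for (s in 1:20) {
    set.seed(3000 + s)
    reads <- seq_records(sprintf("r%d", 1:120),
                         vapply(1:120, function(i)
                           mutate_sequence(tmpl, error_model()),
                           character(1)))
    out <- suppressWarnings(polish_consensus(draft, reads, n = 120,
                                             seed = 2))
    corrected <- corrected + identical(
      substr(out, 150, 164), substr(tmpl, 150, 164))
  }
  expect_equal(corrected, 20L)
})

test_that("homopolymer re-voting restores a run shortened in the draft", {
  # deletion bias kept mild so the modal per-read run length is the true one
  tmpl <- make_reference(400, list(c("A", 8, 150)), seed = 16)
  draft <- paste0(substr(tmpl, 1, 149), substr(tmpl, 151, 400))  # 7-A draft
  model <- error_model(hp_del_multiplier = 1)
  set.seed(137)
  reads <- seq_records(sprintf("r%d", 1:200),
                       vapply(1:200, function(i)
                         mutate_sequence(tmpl, model),
                         character(1)))
  out <- suppressWarnings(polish_consensus(draft, reads, n = 200, seed = 4))
  expect_identical(substr(out, 140, 165), substr(tmpl, 140, 165))
})

test_that("polishing does not decrease identity to the template", {
  set.seed(139)
  worse <- 0L
  n_rep <- 20
  for (s in seq_len(n_rep)) {
    tmpl <- make_reference(300, list(c("T", 6, 120)), seed = 500 + s)
    reads <- seq_records(sprintf("r%d", 1:80),
                         vapply(1:80, function(i)
                           mutate_sequence(tmpl, error_model()),
                           character(1)))
    draft <- plurality_consensus(build_msa(subsample_reads(reads, 60,
                                                           seed = 1)))
    pol <- suppressWarnings(polish_consensus(draft, reads, n = 80, seed = 2))
    acc_d <- evaluate_accuracy(draft, tmpl)$accuracy
    acc_p <- evaluate_accuracy(pol, tmpl)$accuracy
    if (acc_p < acc_d) worse <- worse + 1L
  }
  # sign test: under "polish helps or is neutral", decreases are rare
  expect_lt(stats::binom.test(worse, n_rep, 0.5,
                              alternative = "less")$p.value, 0.05)
  expect_lte(worse, 2)
})

test_that("indel left-normalization is content- and score-preserving", {
  qa <- strsplit("GAAAT", "")[[1]]
  da <- strsplit("GA-AT", "")[[1]]  # insertion placed mid-run
  nm <- barcodetrack:::left_normalize_alignment(qa, da)
  expect_equal(paste(nm$qa[nm$qa != "-"], collapse = ""), "GAAAT")
  expect_equal(paste(nm$da[nm$da != "-"], collapse = ""), "GAAT")
  expect_equal(which(nm$da == "-"), 2L)  # pushed to the leftmost placement

  qd <- strsplit("GAA-T", "")[[1]]
  dd <- strsplit("GAAAT", "")[[1]]  # deletion at the run's right edge
  nm2 <- barcodetrack:::left_normalize_alignment(qd, dd)
  expect_equal(which(nm2$qa == "-"), 2L)
  expect_equal(paste(nm2$qa[nm2$qa != "-"], collapse = ""), "GAAT")
})
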