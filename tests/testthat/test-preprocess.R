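make_tag_pool <- function(n_samples, seed = 5, tag_len = 24) {
  set.seed(seed)
  data.frame(sample_id = sprintf("S%02d", seq_len(n_samples)),
             fwd_tag = vapply(seq_len(n_samples), function(i)
               random_dna(tag_len), character(1)),
             rev_tag = vapply(seq_len(n_samples), function(i)
               random_dna(tag_len), character(1)),
             stringsAsFactors = FALSE)
}

perfect_read <- function(fwd_tag, rev_tag, insert,
                         adapter = "TTTCTGTTGGTGCTGATATTGC",
                         fwd_primer = "GGTCAACAAATCATAAAGATATTGG",
                         rev_primer = "TAAACTTCAGGGTGACCAAAAAATCA") {
  paste0(adapter, fwd_tag, fwd_primer, insert, revcomp(rev_primer),
         revcomp(rev_tag), revcomp(adapter))
}

test_that("dual-tag demultiplexing enforces the both-ends-agree rule", {
  set.seed(31)
  tags <- make_tag_pool(2)
  insert <- random_dna(600)
  r_ok <- perfect_read(tags$fwd_tag[1], tags$rev_tag[1], insert)
  r_mixed <- perfect_read(tags$fwd_tag[1], tags$rev_tag[2], insert)
  r_trunc <- substr(r_ok, 60, nchar(r_ok))  # front tag cut off
  reads <- seq_records(c("ok", "mixed", "trunc"), c(r_ok, r_mixed, r_trunc))
  dmx <- demultiplex(reads, tags)
  expect_equal(dmx$assignments$sample_id, c("S01", "UNASSIGNED", "UNASSIGNED"))
  expect_equal(dmx$samples$S01$id, "ok")
  # conservation: every read lands in exactly one bucket
  n_bucketed <- sum(vapply(dmx$samples, nrow, integer(1))) +
    nrow(dmx$unassigned)
  expect_equal(n_bucketed, nrow(reads))
})

test_that("demultiplexing conserves reads on noisy pools", {
  sim <- make_sim_sample(n_reads = 120, seed = 13)
  dmx <- demultiplex(sim$reads, sim$tags)
  expect_equal(nrow(dmx$samples$S1) + nrow(dmx$unassigned), 120)
})

test_that("misassignment on a 12-sample pool at 12% error is below 0.1%", {
  tags <- make_tag_pool(12, seed = 77)
  ref <- default_reference(3)
  pool <- do.call(rbind, lapply(seq_len(12), function(i) {
    tmpl <- barcode_template(ref, fwd_tag = tags$fwd_tag[i],
                             rev_tag = tags$rev_tag[i])
    rd <- simulate_sample(tmpl, 120, rng_seed = 1000 + i, contam_frac = 0)
    rd$id <- paste0(tags$sample_id[i], "_", rd$id)
    rd
  }))
  class(pool) <- c("seq_records", "data.frame")
  dmx <- demultiplex(pool, tags)
  asg <- dmx$assignments
  assigned <- asg[asg$sample_id != "UNASSIGNED", ]
  truth <- sub("_read.*$", "", assigned$read_id)
  mis <- mean(truth != assigned$sample_id)
  expect_lt(mis, 0.001)
  expect_gt(nrow(assigned) / nrow(pool), 0.9)  # demux keeps most reads
})

test_that("trimming recovers the primer-flanked core and normalizes strand", {
  set.seed(19)
  tags <- make_tag_pool(1)
  insert <- random_dna(600)
  fwd_primer <- "GGTCAACAAATCATAAAGATATTGG"
  rev_primer <- "TAAACTTCAGGGTGACCAAAAAATCA"
  core <- paste0(fwd_primer, insert, revcomp(rev_primer))
  r_fwd <- perfect_read(tags$fwd_tag[1], tags$rev_tag[1], insert)
  r_rev <- revcomp(r_fwd)
  # two substitutions inside the front tag must not move the boundary
  flip <- function(s, i) {
    b <- c(A = "C", C = "G", G = "T", T = "A")[[substr(s, i, i)]]
    substr(s, i, i) <- b
    s
  }
  tag_err <- flip(flip(tags$fwd_tag[1], 5), 12)
  r_sub <- perfect_read(tag_err, tags$rev_tag[1], insert)
  reads <- seq_records(c("fwd", "rev", "sub"), c(r_fwd, r_rev, r_sub))
  tr <- trim_ends(reads, tags$fwd_tag[1], tags$rev_tag[1])
  expect_equal(tr$seq[1], core)
  expect_equal(tr$seq[2], core)  # reverse strand re-oriented
  expect_equal(tr$seq[3], core)  # boundary located despite tag errors
})

test_that("an unlocatable boundary leaves the end untrimmed with a warning", {
  set.seed(23)
  tags <- make_tag_pool(1)
  bare <- random_dna(400)  # no tags anywhere
  expect_warning(
    tr <- trim_ends(seq_records("x", bare), tags$fwd_tag[1], tags$rev_tag[1],
                    min_identity = 0.9),
    "untrimmed")
  expect_equal(nchar(tr$seq), 400)
})

test_that("length filter reproduces the 2-SD retention window exactly", {
  # constructed set: mean 682, population SD 16
  lens <- c(650, 714, rep(682, 6))
  set.seed(41)
  reads <- seq_records(sprintf("r%d", seq_along(lens)),
                       vapply(lens, random_dna, character(1)))
  lf <- length_filter(reads, k = 2)
  expect_equal(lf$report$mean_len, 682)
  expect_equal(lf$report$sd_len, 16)
  expect_equal(lf$report$low_bound, 650)
  expect_equal(lf$report$high_bound, 714)
  expect_equal(lf$report$n_retained, 8)  # boundary lengths are retained
  # the SD multiplier recovered from the window is exactly 2
  expect_equal((lf$report$mean_len - lf$report$low_bound) / lf$report$sd_len,
               2)
  expect_true(all(nchar(lf$records$seq) >= lf$report$low_bound &
                  nchar(lf$records$seq) <= lf$report$high_bound))
})

test_that("length filter matches a brute-force arithmetic oracle", {
  lens <- c(600, 680, 681, 682, 683, 684, 900)
  set.seed(43)
  reads <- seq_records(sprintf("r%d", seq_along(lens)),
                       vapply(lens, random_dna, character(1)))
  m <- mean(lens)
  s <- sqrt(mean((lens - m)^2))
  keep_oracle <- lens >= m - 2 * s & lens <= m + 2 * s
  lf <- length_filter(reads, k = 2)
  expect_identical(lf$records$id, reads$id[keep_oracle])
  expect_identical(sort(setdiff(reads$id, lf$records$id)),
                   reads$id[!keep_oracle])
})

test_that("identical lengths are all retained and refiltering is stable", {
  set.seed(47)
  same <- seq_records(sprintf("r%d", 1:5),
                      vapply(rep(300, 5), random_dna, character(1)))
  lf <- length_filter(same)
  expect_equal(lf$report$n_retained, 5)

  sim <- make_sim_sample(n_reads = 400, seed = 29)
  lf1 <- length_filter(sim$reads)
  lf2 <- length_filter(lf1$records)
  removed_again <- lf1$report$n_retained - lf2$report$n_retained
  expect_lte(removed_again, 0.05 * lf1$report$n_retained)
})

test_that("fewer than two reads skip the filter with a warning", {
  one <- seq_records("only", random_dna(100))
  expect_warning(lf <- length_filter(one), "fewer than 2")
  expect_equal(nrow(lf$records), 1)
})
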