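test_that("reference geometry and truth levels obey the block design", {
  ref <- make_reference(100, 500, repeat_fraction = 0.2, seed = 1)
  expect_length(ref$seq, 50000L)
  expect_equal(nrow(ref$truth), 100L)
  expect_true(all(ref$truth$end - ref$truth$start + 1L == 500L))
  expect_true(all(ref$truth$true_mcg >= 0 & ref$truth$true_mcg <= 1))
  expect_true(all(ref$truth$true_mch >= 0 & ref$truth$true_mch <= 1))
  expect_equal(sum(ref$truth$is_repeat), 20L)
  expect_error(make_reference(0), "n_blocks")
})

test_that("the same seed reproduces reference, truth and reads exactly", {
  a <- make_reference(20, 500, seed = 9)
  b <- make_reference(20, 500, seed = 9)
  expect_identical(a$seq, b$seq)
  expect_identical(a$truth, b$truth)
  ra <- generate_reads(a, 50, error_rate = 0.04, seed = 3)
  rb <- generate_reads(b, 50, error_rate = 0.04, seed = 3)
  expect_identical(ra$bases, rb$bases)
  expect_identical(ra$realized, rb$realized)
})

test_that("repeat_fraction zero yields no duplicated blocks", {
  ref <- make_reference(30, 200, repeat_fraction = 0, seed = 2)
  blocks <- vapply(seq_len(30), function(b)
    paste(ref$seq[((b - 1) * 200 + 1):(b * 200)], collapse = ""), "")
  expect_false(any(duplicated(blocks)))
  expect_false(any(ref$truth$is_repeat))
})

test_that("context classification marks CG/CHG/CHH from downstream bases", {
  ref <- make_reference(2, 100, seed = 4)
  isC <- ref$seq == "C"
  expect_true(all(is.na(ref$context[!isC])))
  idx <- which(isC & seq_along(ref$seq) <= length(ref$seq) - 2)
  for (i in sample(idx, 30)) {
    expected <- if (ref$seq[i + 1] == "G") "CG"
      else if (ref$seq[i + 2] == "G") "CHG" else "CHH"
    expect_equal(ref$context[i], expected)
  }
})

test_that("fully unmethylated blocks convert every cytosine to T", {
  ref <- make_reference(4, 300, repeat_fraction = 0, seed = 5)
  ref$truth$true_mcg <- 0
  ref$truth$true_mch <- 0
  reads <- generate_reads(ref, 80, reads_per_block = 10, error_rate = 0,
                          seed = 5)
  posmat <- outer(reads$start, 0:79, `+`)
  cmask <- matrix(ref$seq[posmat] == "C", nrow = nrow(posmat))
  expect_true(all(reads$bases[cmask] == "T"))
  expect_equal(reads$realized$realized_mcg, rep(0, 4))
})

test_that("fully methylated error-free reads equal the reference substring", {
  ref <- make_reference(4, 300, repeat_fraction = 0, seed = 6)
  ref$truth$true_mcg <- 1
  ref$truth$true_mch <- 1
  reads <- generate_reads(ref, 60, reads_per_block = 5, error_rate = 0,
                          seed = 6)
  for (i in seq_len(nrow(reads$bases))) {
    expect_identical(reads$bases[i, ],
                     ref$seq[reads$start[i]:(reads$start[i] + 59)])
  }
})

test_that("default read numbers hit 10x coverage and stay inside blocks", {
  ref <- make_reference(3, 500, seed = 7)
  for (L in c(100L, 50L)) {
    reads <- generate_reads(ref, L, error_rate = 0, seed = 7)
    expect_equal(reads$reads_per_block, 500L * 10L / L)
    expect_equal(nrow(reads$bases) * L / length(ref$seq), 10)
    blk_start <- ref$truth$start[reads$block_id]
    expect_true(all(reads$start >= blk_start))
    expect_true(all(reads$start + L - 1L <= blk_start + 499L))
  }
  expect_error(generate_reads(ref, 501), "read_length")
})

test_that("realized conversion converges to the drawn truth (binomial)", {
  ref <- make_reference(1, 500, repeat_fraction = 0, seed = 8)
  reads <- generate_reads(ref, 50, reads_per_block = 10000, error_rate = 0,
                          seed = 8)
  sites <- reads$realized_sites
  for (ctx in c("CG", "CH")) {
    sel <- if (ctx == "CG") sites$context == "CG" else sites$context != "CG"
    n_obs <- sum(sites$n[sel])
    p <- if (ctx == "CG") ref$truth$true_mcg[1] else ref$truth$true_mch[1]
    realized <- sum(sites$n_meth[sel]) / n_obs
    se <- sqrt(p * (1 - p) / n_obs)
    expect_lt(abs(realized - p), 3 * se + 1e-9)
  }
})

test_that("sequencing errors hit the configured per-base rate", {
  ref <- make_reference(20, 500, seed = 10)
  reads <- generate_reads(ref, 100, error_rate = 0.06, seed = 10)
  rate <- mean(reads$n_errors) / 100
  se <- sqrt(0.06 * 0.94 / (nrow(reads$bases) * 100))
  expect_lt(abs(rate - 0.06), 4 * se)
})

test_that("a perfect mapper maps everything correctly and conserves coverage", {
  ref <- make_reference(10, 500, seed = 11)
  reads <- generate_reads(ref, 100, error_rate = 0, seed = 11)
  perfect <- mapper_profile("perfect", base_map_rate = 1)
  emu <- emulate_mapper(reads, ref, perfect, seed = 11)
  expect_equal(mapping_rate(emu$outcomes), 1)
  expect_equal(mapping_accuracy(emu$outcomes), 1)
  # coverage conservation: every covered reference C contributes one call
  csum <- cumsum(ref$seq == "C")
  per_read <- csum[reads$start + 99L] -
    ifelse(reads$start > 1L, csum[reads$start - 1L], 0L)
  expect_equal(sum(emu$callset$calls$depth), sum(per_read))
  expect_equal(emu$callset$lam,
               sum(emu$callset$calls$depth) / ref$n_cytosines)
})

test_that("an always-mismapping profile has zero mapping accuracy", {
  ref <- make_reference(5, 300, seed = 12)
  reads <- generate_reads(ref, 50, reads_per_block = 20, error_rate = 0,
                          seed = 12)
  bad <- mapper_profile("bad", base_map_rate = 1, mismap_rate_base = 1)
  emu <- emulate_mapper(reads, ref, bad, seed = 12)
  expect_equal(mapping_accuracy(emu$outcomes), 0)
  expect_equal(mapping_rate(emu$outcomes), 1)
})

test_that("T-rich reads are preferentially mismapped when T-sensitive", {
  ref <- make_reference(100, 500, seed = 13)
  reads <- generate_reads(ref, 100, error_rate = 0, seed = 13)  # 5000 reads
  prof <- mapper_profile("tsens", base_map_rate = 1,
                         mismap_rate_base = 0.05,
                         t_density_sensitivity = 0.5)
  emu <- emulate_mapper(reads, ref, prof, seed = 13)
  ts <- t_density_summary(emu$outcomes)
  expect_gt(ts[outcome == "mismapped", mean_t_fraction],
            ts[outcome == "correct", mean_t_fraction])
})

test_that("preset profiles reproduce the published mapper orderings", {
  p <- preset_profiles()
  expect_setequal(names(p), c("bismark-like", "bsmap-like", "bsseeker2-like"))
  for (pr in p) {
    expect_true(all(unlist(pr[c("base_map_rate", "mismap_rate_base")]) >= 0))
    expect_true(all(unlist(pr[c("base_map_rate", "mismap_rate_base")]) <= 1))
  }
  rate_at <- function(pr, err) min(1, max(0,
    pr$base_map_rate - pr$error_sensitivity * err))
  # wild-card mapper maps more clean reads, but collapses at high error
  expect_gt(rate_at(p[["bsmap-like"]], 0.02), rate_at(p[["bismark-like"]], 0.02))
  drop_bss <- rate_at(p[["bsseeker2-like"]], 0) -
    rate_at(p[["bsseeker2-like"]], 0.08)
  drop_bsmap <- rate_at(p[["bsmap-like"]], 0) - rate_at(p[["bsmap-like"]], 0.08)
  expect_lt(drop_bss, drop_bsmap)
  # only the three-letter error-tolerant mapper keeps its rate at 8% error
  expect_gt(rate_at(p[["bsseeker2-like"]], 0.08), 0.7)
})

test_that("redrawing truth keeps the sequence but changes the levels", {
  a <- make_reference(20, 300, seed = 14)
  b <- redraw_truth(a, seed = 99)
  expect_identical(a$seq, b$seq)
  expect_identical(a$truth$is_repeat, b$truth$is_repeat)
  expect_false(any(a$truth$true_mcg == b$truth$true_mcg))
})

test_that("FASTQ export encodes the true origin in read names", {
  ref <- make_reference(2, 200, seed = 15)
  reads <- generate_reads(ref, 50, reads_per_block = 3, error_rate = 0,
                          seed = 15)
  f <- withr::local_tempfile(fileext = ".fastq")
  export_reads_fastq(reads, f)
  lines <- readLines(f)
  expect_length(lines, 4L * 6L)
  expect_match(lines[1], sprintf("^@read1:%s:%d:\\+$", ref$chrom,
                                 reads$start[1]))
  expect_equal(nchar(lines[2]), 50L)
  fa <- withr::local_tempfile(fileext = ".fa")
  export_reference_fasta(ref, fa)
  expect_match(readLines(fa)[1], "^>")
})
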