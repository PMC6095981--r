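qchar <- function(q, n) strrep(intToUtf8(q + 33L), n)

mk_pairs <- function(r1, r2, q1 = NULL, q2 = NULL) {
  n <- length(r1)
  list(r1 = r1,
       q1 = q1 %||% vapply(nchar(r1), function(L) qchar(40, L), character(1)),
       r2 = r2,
       q2 = q2 %||% vapply(nchar(r2), function(L) qchar(40, L), character(1)),
       ids = sprintf("read%02d", seq_len(n)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("quality filter applies a strict median-Phred threshold to both mates", {
  set.seed(1)
  s <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  half <- paste0(qchar(30, 50), qchar(40, 50))  # median 35
  pairs <- mk_pairs(r1 = rep(s, 3), r2 = rep(s, 3),
                    q1 = c(qchar(40, 100), qchar(30, 100), half),
                    q2 = rep(qchar(40, 100), 3))
  out <- quality_filter(pairs, min_median_phred = 34)
  expect_identical(out$ids, c("read01", "read03"))
  expect_equal(attr(out, "n_removed"), 1L)
  # threshold is strict: a median of exactly 34 fails
  pairs34 <- mk_pairs(s, s, q1 = qchar(34, 100), q2 = qchar(40, 100))
  expect_length(quality_filter(pairs34)$ids, 0L)
})

test_that("pairs merge only on an identical overlap longer than 50 bp", {
  set.seed(2)
  amp <- paste(sample(c("A", "C", "G", "T"), 170, replace = TRUE),
               collapse = "")
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  # 60 bp exact overlap: r1 = amp[1:110], r2 covers amp[51:160]
  r1 <- substr(amp, 1, 110)
  r2_60 <- rc(substr(amp, 51, 160))
  m <- merge_pairs(mk_pairs(r1, r2_60))
  expect_equal(nrow(m), 1L)
  expect_equal(nchar(m$sequence), 110 + 110 - 60)
  expect_identical(m$sequence, substr(amp, 1, 160))
  # exactly 50 bp overlap is rejected (strictly greater required)
  r2_50 <- rc(substr(amp, 61, 170))
  expect_equal(nrow(merge_pairs(mk_pairs(r1, r2_50))), 0L)
  # one mismatch inside a 60 bp overlap is rejected
  bad <- substr(amp, 51, 160)
  mid <- substr(bad, 30, 30)
  substr(bad, 30, 30) <- setdiff(c("A", "C", "G", "T"), mid)[1]
  expect_equal(nrow(merge_pairs(mk_pairs(r1, rc(bad)))), 0L)
})

test_that("barcode extraction validates conserved T bases on either strand", {
  body <- strrep("G", 120)
  good <- paste0("AAAATAAAATAAAAT", body)
  merged <- data.table::data.table(
    read_id = c("a", "b", "c"),
    sequence = c(good,
                 as.character(Biostrings::reverseComplement(
                   Biostrings::DNAString(good))),
                 paste0("AAAATAAAACAAAAT", body)))  # C at position 10
  out <- extract_barcode(merged)
  expect_equal(nrow(out), 2L)
  expect_equal(attr(out, "n_rejected"), 1L)
  expect_identical(out$barcode, rep("AAAATAAAATAAAAT", 2))
  expect_identical(out$sequence[1], body)
  expect_identical(out$sequence[2], body)  # flipped back to forward
  expect_identical(out$flipped, c(FALSE, TRUE))
})

test_that("isotype k-mer scores match brute-force shared 10-mer counts", {
  gs <- test_germline()
  set.seed(3)
  vpart <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
                 collapse = "")
  for (iso in c("IGHG1", "IGHA1", "IGHE")) {
    pre <- substr(gs$c$seq[gs$c$isotype == iso], 1, 50)
    read <- paste0(vpart, pre)
    res <- assign_isotype(read, gs, return_scores = TRUE)
    expect_identical(res$call, iso)
    expect_equal(unname(res$scores[1, iso]), 41)
    # one central mismatch destroys the 10 windows covering it
    mut <- pre
    substr(mut, 25, 25) <- setdiff(c("A", "C", "G", "T"),
                                   substr(pre, 25, 25))[1]
    read2 <- paste0(vpart, mut)
    res2 <- assign_isotype(read2, gs, return_scores = TRUE)
    expect_identical(res2$call, iso)
    tail2 <- substr(read2, nchar(read2) - 59, nchar(read2))
    expect_equal(unname(res2$scores[1, iso]), r_kmer_score(tail2, pre))
    expect_equal(unname(res2$scores[1, iso]), 31)
  }
  # no shared 10-mer with any gene -> ambiguous
  expect_identical(assign_isotype(strrep("A", 120), gs), "ambiguous")
})

test_that("consensus certainty is mean per-position majority support", {
  r <- strrep("ACGT", 25)
  out <- build_consensus(rep(r, 3))
  expect_identical(out$consensus, r)
  expect_equal(out$certainty, 1.0)
  expect_true(out$retained)
  # 2 reads of length 100 differing at 25 positions -> certainty 0.875
  a <- strrep("A", 100)
  b <- paste0(strrep("C", 25), strrep("A", 75))
  out2 <- build_consensus(c(a, b))
  expect_equal(out2$certainty, (75 * 1 + 25 * 0.5) / 100)
  expect_true(out2$retained)
  expect_identical(out2$consensus, a)  # ties break towards A < C
  # 45 differing positions -> certainty 0.775 < 0.8 -> discarded
  b45 <- paste0(strrep("C", 45), strrep("A", 55))
  out3 <- build_consensus(c(a, b45))
  expect_equal(out3$certainty, 0.775)
  expect_false(out3$retained)
  expect_error(build_consensus(character(0)), "empty")
})

test_that("mixed read lengths keep only the modal length", {
  out <- build_consensus(c(strrep("A", 100), strrep("A", 100),
                           strrep("A", 80)))
  expect_equal(out$n_used, 2L)
  expect_equal(out$n_dropped_length, 1L)
  expect_equal(out$read_count, 3L)
  expect_equal(nchar(out$consensus), 100L)
})

test_that("pre-correction error rate uses total member bases as denominator", {
  a <- strrep("A", 100)
  b <- paste0("CC", strrep("A", 98))  # 2 mismatches to consensus (= a)
  reads <- data.table::data.table(
    barcode = c("BC1", "BC1", "BC2"),
    sequence = c(a, b, a))
  cons <- consensus_by_barcode(reads, const_trim = 0L)
  err <- estimate_precorrection_error(cons)
  expect_equal(err$rate, 2 / 200)
  expect_equal(err$n_groups, 1L)  # singleton group excluded
  # noiseless groups give exactly zero
  reads0 <- data.table::data.table(barcode = rep("BC1", 3),
                                   sequence = rep(a, 3))
  expect_equal(estimate_precorrection_error(
    consensus_by_barcode(reads0, const_trim = 0L))$rate, 0)
  # no multi-read group -> flagged NA
  single <- consensus_by_barcode(
    data.table::data.table(barcode = "B1", sequence = a), const_trim = 0L)
  est <- estimate_precorrection_error(single)
  expect_true(is.na(est$rate))
  expect_true(est$flagged)
})

test_that("lowering the certainty threshold never loses groups", {
  gs <- test_germline()
  sim <- simulate_repertoire(gs, sim_config(
    n_clones = 20, pb_given_switched = 0, pb_given_unswitched = 0), seed = 4)
  mc <- emit_molecule_copies(sim, gs, error_rate = 0.03, copies_min = 2,
                             seed = 5)
  retained <- vapply(c(0.95, 0.9, 0.8, 0.5, 0), function(th) {
    cb <- consensus_by_barcode(mc$reads, certainty_threshold = th)
    sum(cb$groups$retained)
  }, numeric(1))
  expect_true(all(diff(retained) >= 0))
})

test_that("frame/Ig filter drops non-Ig and stop-containing sequences", {
  gs <- test_germline()
  sim <- simulate_repertoire(gs, sim_config(n_clones = 10), seed = 6)
  seqs <- sim$cells$sequence[1:5]
  set.seed(7)
  random_seq <- paste(sample(c("A", "C", "G", "T"), nchar(seqs[1]),
                             replace = TRUE), collapse = "")
  stopped <- seqs[2]
  substr(stopped, 10, 12) <- "TAA"  # in-frame stop planted in the V region
  dt <- data.table::data.table(sequence = c(seqs, random_seq, stopped))
  out <- frame_and_ig_filter(dt, gs)
  expect_identical(out$sequence, seqs)
  expect_equal(attr(out, "n_removed"), 2L)
})

test_that("noiseless molecule copies collapse to exact consensus sequences", {
  gs <- test_germline()
  sim <- simulate_repertoire(gs, sim_config(
    n_clones = 25, pb_given_switched = 0, pb_given_unswitched = 0), seed = 8)
  mc <- emit_molecule_copies(sim, gs, error_rate = 0, copies_min = 2, seed = 9)
  cons <- consensus_by_barcode(mc$reads)
  expect_equal(nrow(cons$groups), nrow(mc$molecules))
  m <- merge(cons$groups, mc$molecules, by = "barcode")
  expect_true(all(m$consensus == m$sequence))
  expect_true(all(m$certainty == 1))
  err <- estimate_precorrection_error(cons)
  expect_equal(err$rate, 0)
})
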