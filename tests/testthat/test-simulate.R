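test_that("zero SHM rate yields unmutated cells identical to germline", {
  gs <- test_germline()
  cfg <- sim_config(n_clones = 40, founder_shm_rate = 0, p_shm_step = 0,
                    switch_matrix = default_switch_matrix(identity = TRUE))
  sim <- simulate_repertoire(gs, cfg, seed = 5)
  expect_true(all(sim$cells$n_shm_total == 0))
  expect_true(all(sim$cells$isotype %in% c("IGHM", "IGHD")))
  germ <- setNames(sim$clones$germline_seq, sim$clones$clone_id)
  expect_true(all(sim$cells$sequence == germ[as.character(sim$cells$clone_id)]))
})

test_that("identity switch matrix retains initial isotypes with no events", {
  gs <- test_germline()
  cfg <- sim_config(n_clones = 60,
                    switch_matrix = default_switch_matrix(identity = TRUE))
  sim <- simulate_repertoire(gs, cfg, seed = 6)
  expect_true(all(sim$cells$isotype %in% c("IGHM", "IGHD")))
  expect_equal(nrow(sim$events), 0L)
  ut <- unique_bcr_table(cells_to_bcr_table(sim, gs))
  ov <- overlap_coefficients(ut, seed = 1)
  expect_true(ov$flagged)
  expect_true(all(ov$mean == 0))
})

test_that("geometric clone sizes have the configured mean", {
  gs <- test_germline()
  p <- 0.1
  cfg <- sim_config(n_clones = 50, clone_p = p, p_naive = 0)
  sim <- simulate_repertoire(gs, cfg, seed = 3)
  sizes <- table(sim$cells$clone_id)
  expect_equal(length(sizes), 50L)
  # mean of 1 + Geom(p) is 1/p, variance (1-p)/p^2
  se <- sqrt((1 - p) / p^2 / 50)
  expect_lt(abs(mean(sizes) - 1 / p), 3 * se)
})

test_that("switching is restricted to downstream constant genes", {
  gs <- test_germline()
  sim <- simulate_repertoire(gs, sim_config(n_clones = 150), seed = 8)
  ord <- setNames(seq_along(IGH_ISOTYPES), IGH_ISOTYPES)
  expect_true(all(ord[sim$events$to_iso] > ord[sim$events$from_iso]))
  expect_error(
    sim_config(switch_matrix = {
      m <- default_switch_matrix(); m[3, 1] <- m[3, 3]; m[3, 3] <- 0; m
    }),
    "deletional")
  expect_error(
    sim_config(switch_matrix = {
      m <- default_switch_matrix(); m[1, 9] <- m[1, 9] + 0.01; m
    }),
    "sum to 1")
})

test_that("read emission is deterministic and conserves molecules", {
  gs <- test_germline()
  sim <- simulate_repertoire(gs, sim_config(
    n_clones = 15, pb_given_switched = 0, pb_given_unswitched = 0), seed = 2)
  d <- tempdir()
  f1a <- file.path(d, "a_R1.fastq.gz"); f2a <- file.path(d, "a_R2.fastq.gz")
  f1b <- file.path(d, "b_R1.fastq.gz"); f2b <- file.path(d, "b_R2.fastq.gz")
  rd1 <- emit_reads(sim, gs, error_rate = 0.004, pcr_duplicates = 1, seed = 4,
                    r1_path = f1a, r2_path = f2a)
  rd2 <- emit_reads(sim, gs, error_rate = 0.004, pcr_duplicates = 1, seed = 4,
                    r1_path = f1b, r2_path = f2b)
  p1 <- read_fastq_pair(f1a, f2a)
  p2 <- read_fastq_pair(f1b, f2b)
  expect_identical(p1, p2)
  # conservation: distinct barcodes == number of molecules
  expect_equal(length(unique(rd1$molecules$barcode)), nrow(rd1$molecules))
  expect_equal(nrow(rd1$molecules), sum(sim$cells$rna_copies))
  # ground-truth completeness: every read id resolves to a molecule and cell
  expect_true(all(rd1$reads$molecule_id %in% rd1$molecules$molecule_id))
  expect_true(all(rd1$molecules$cell_id %in% sim$cells$cell_id))
})

test_that("emitted barcodes carry the conserved T bases", {
  gs <- test_germline()
  sim <- simulate_repertoire(gs, sim_config(
    n_clones = 10, pb_given_switched = 0, pb_given_unswitched = 0), seed = 2)
  rd <- emit_reads(sim, gs, error_rate = 0, pcr_duplicates = 0, seed = 1)
  bc <- rd$molecules$barcode
  expect_true(all(nchar(bc) == 15))
  expect_true(all(substr(bc, 5, 5) == "T"))
  expect_true(all(substr(bc, 10, 10) == "T"))
  expect_true(all(substr(bc, 15, 15) == "T"))
})

test_that("noiseless emission yields identical reads per barcode", {
  gs <- test_germline()
  sim <- simulate_repertoire(gs, sim_config(
    n_clones = 10, pb_given_switched = 0, pb_given_unswitched = 0), seed = 2)
  rd <- emit_reads(sim, gs, error_rate = 0, pcr_duplicates = 2, seed = 1)
  per_mol <- split(rd$r1, rd$reads$molecule_id)
  expect_true(all(vapply(per_mol, function(x) length(unique(x)) == 1L,
                         logical(1))))
})

test_that("injected substitution errors match the configured rate", {
  gs <- test_germline()
  sim <- simulate_repertoire(gs, sim_config(
    n_clones = 60, pb_given_switched = 0, pb_given_unswitched = 0), seed = 2)
  target <- 0.004
  rd <- emit_reads(sim, gs, error_rate = target, pcr_duplicates = 1, seed = 9)
  cmap <- setNames(test_germline()$c$seq, test_germline()$c$isotype)
  amp <- paste0(rd$molecules$barcode, rd$molecules$sequence,
                substr(cmap[rd$molecules$isotype], 1, 60))
  L <- rd$params$read_length
  true_r1 <- substr(amp[rd$reads$molecule_id], 1, L)
  mm <- sum(mapply(function(a, b) sum(charToRaw(a) != charToRaw(b)),
                   rd$r1, true_r1))
  n_bases <- length(rd$r1) * L
  se <- sqrt(target * (1 - target) / n_bases)
  expect_lt(abs(mm / n_bases - target), 3 * se)
  # Phred strings consistent with the error model: high-quality bases are
  # nearly error free
  q <- utf8ToInt(paste(rd$q1, collapse = "")) - 33L
  flat_true <- unlist(strsplit(true_r1, ""))
  flat_obs <- unlist(strsplit(rd$r1, ""))
  hi <- q == 40L
  expect_lt(mean(flat_obs[hi] != flat_true[hi]), 0.001)
  expect_gt(mean(flat_obs[!hi] != flat_true[!hi]), 0.005)
})

test_that("amplicons incompatible with the read layout raise an error", {
  gs <- test_germline()
  sim <- simulate_repertoire(gs, sim_config(n_clones = 5), seed = 2)
  expect_error(emit_reads(sim, gs, read_length = 400L, seed = 1),
               "configuration error")
  expect_error(emit_reads(sim, gs, error_rate = 0.2, seed = 1), "error_rate")
})

test_that("simulation is reproducible given seed and config", {
  gs <- test_germline()
  s1 <- simulate_repertoire(gs, sim_config(n_clones = 25), seed = 10)
  s2 <- simulate_repertoire(gs, sim_config(n_clones = 25), seed = 10)
  expect_identical(s1$cells, s2$cells)
  expect_identical(s1$events, s2$events)
})
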