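test_that("isotype frequencies count unique presence events", {
  # all records IgM -> 100%
  f <- isotype_frequencies(unique_bcr_table(
    mk_tab(c("AAAA", "CCCC"), c("IGHM", "IGHM"))), scheme = "class")
  expect_equal(f$freq, 100)
  expect_identical(f$isotype_group, "IgM")
  # one IgM-only sequence plus one in IgM and IgG1: denominator 3 presences
  f2 <- isotype_frequencies(unique_bcr_table(
    mk_tab(c("AAAA", "CCCC", "CCCC"), c("IGHM", "IGHM", "IGHG1"))),
    scheme = "class")
  expect_equal(f2$freq[f2$isotype_group == "IgM"], 100 * 2 / 3,
               tolerance = 1e-12)
  expect_equal(f2$freq[f2$isotype_group == "IgG1/2"], 100 / 3,
               tolerance = 1e-12)
  expect_equal(sum(f2$freq), 100)
  expect_error(isotype_frequencies(unique_bcr_table(mk_tab(
    character(0), character(0)))), "empty")
})

test_that("unique-BCR counting removes the plasmablast RNA skew", {
  gs <- test_germline()
  sim <- simulate_repertoire(gs, sim_config(n_clones = 800), seed = 31)
  ut <- unique_bcr_table(cells_to_bcr_table(sim, gs))
  uf <- isotype_frequencies(ut, weight = "unique")
  rf <- isotype_frequencies(ut, weight = "reads")
  cellmix <- sim$cells[, .N, by = .(isotype_group = group_isotypes(isotype))]
  cellmix[, pct := 100 * N / sum(N)]
  m <- merge(merge(uf[, .(isotype_group, unique_pct = freq)],
                   rf[, .(isotype_group, read_pct = freq)],
                   by = "isotype_group"),
             cellmix, by = "isotype_group")
  expect_lt(max(abs(m$unique_pct - m$pct)), 3)
  expect_gt(max(abs(m$read_pct - m$pct)), 10)
})

test_that("per-sample summaries report the named statistics", {
  tab <- mk_tab("AAAA", "IGHM", junction_aa = strrep("W", 15),
                n_mut_silent = 3L, n_mut_nonsilent = 5L, n_mut_total = 8L)
  s <- sample_summaries(unique_bcr_table(tab))
  expect_equal(s$mean_cdr3_length, 15)
  expect_equal(s$median_mut_silent, 3)
  expect_equal(s$median_mut_nonsilent, 5)
  tab3 <- mk_tab(c("AAAA", "CCCC", "GGGG"), "IGHM",
                 n_mut_silent = c(0L, 2L, 4L))
  expect_equal(sample_summaries(unique_bcr_table(tab3))$median_mut_silent, 2)
})

test_that("switched isotypes carry more SHM in a GC-style simulation", {
  gs <- test_germline()
  sim <- simulate_repertoire(gs, sim_config(n_clones = 400), seed = 32)
  s <- sample_summaries(unique_bcr_table(cells_to_bcr_table(sim, gs)),
                        scheme = "overlap")
  md <- s[s$isotype_group == "IgD/M"]
  sw <- s[s$isotype_group != "IgD/M"]
  expect_lt(md$median_mut_nonsilent, mean(sw$median_mut_nonsilent))
})

test_that("overlap coefficients count sequences in exactly two classes", {
  # u1 in {IgM, IgA1}; u2 in {IgM}; u3 in {IgM, IgA1, IgG1}: only u1 counts
  tab <- mk_tab(c("AAAA", "AAAA", "CCCC", "GGGG", "GGGG", "GGGG"),
                c("IGHM", "IGHA1", "IGHM", "IGHM", "IGHA1", "IGHG1"))
  ov <- overlap_coefficients(unique_bcr_table(tab), seed = 1)
  expect_false(ov$subsampled)  # below depth: one full pass, flagged as such
  expect_equal(ov$mean["IgD/M", "IgA1/2"], 1)
  expect_equal(sum(ov$mean[upper.tri(ov$mean)]), 1)
  expect_identical(ov$mean, t(ov$mean))
  # no sharing at all -> zero matrix, flagged
  ov0 <- overlap_coefficients(unique_bcr_table(
    mk_tab(c("AAAA", "CCCC"), c("IGHM", "IGHG1"))), seed = 1)
  expect_true(ov0$flagged)
  expect_true(all(ov0$mean == 0))
})

test_that("subsampled overlap matrices are symmetric, normalised and stable", {
  gs <- test_germline()
  sim <- simulate_repertoire(gs, sim_config(n_clones = 1200), seed = 33)
  ut <- unique_bcr_table(cells_to_bcr_table(sim, gs))
  expect_gt(sum(ut$duplicate_count), 50000)
  ov <- overlap_coefficients(ut, depth = 8000, n_sub = 20, seed = 34)
  expect_true(ov$subsampled)
  expect_identical(ov$mean, t(ov$mean))
  expect_equal(sum(ov$mean[upper.tri(ov$mean)]), 1, tolerance = 1e-9)
  expect_true(all(ov$se[upper.tri(ov$se)] < 0.05))
})

test_that("conditional switch probabilities are the stated count ratios", {
  # gene X: 100 unique BCRs, 40 mutated, 30 of the mutated switched
  seqs <- sprintf("SEQ%03d", 1:100)
  iso <- c(rep("IGHG1", 30), rep("IGHM", 70))      # switched = first 30
  mut <- c(rep(1L, 40), rep(0L, 60))               # mutated = first 40
  tab <- mk_tab(seqs, iso, n_mut_total = mut, v_call = "IGHV1-x")
  sp <- switch_probabilities(unique_bcr_table(tab), min_reads = 0)
  g <- sp$gene
  expect_equal(g$fx, 100L)
  expect_equal(g$p_mutated, 0.40)
  expect_equal(g$p_unmutated, 0.60)
  expect_equal(g$p_switched_mutated, 30 / 40)
  expect_equal(g$p_switched_unmutated, 0)
  expect_equal(g$p_mutated + g$p_unmutated, 1)
  # all-unmutated IgM -> switching probability zero
  sp0 <- switch_probabilities(unique_bcr_table(
    mk_tab(sprintf("Q%02d", 1:20), "IGHM")), min_reads = 0)
  expect_equal(sp0$gene$p_switched, 0)
  expect_true(is.na(sp0$gene$p_switched_mutated))  # empty denominator
})

test_that("probability identities hold on simulated repertoires", {
  gs <- test_germline()
  for (seed in c(41, 42)) {
    sim <- simulate_repertoire(gs, sim_config(n_clones = 500), seed = seed)
    ut <- unique_bcr_table(cells_to_bcr_table(sim, gs))
    sp <- switch_probabilities(ut, min_reads = 100)
    expect_true(all(abs(sp$gene$p_mutated + sp$gene$p_unmutated - 1) < 1e-12))
    sums <- sp$isotype[, .(s = sum(p_isotype_given_switched)), by = gene]
    expect_true(all(abs(sums$s - 1) < 1e-12))
    expect_true(all(sp$gene$p_switched >= 0 & sp$gene$p_switched <= 1))
  }
})

test_that("per-gene switch probabilities are recovered from simulation", {
  gs <- make_germline_set(4, 3, 2, seed = 51)
  spv <- setNames(c(0.6, 0.2, 0.6, 0.2), gs$v$name)
  cfg <- sim_config(n_clones = 500, p_naive = 0, p_shm_step = 1,
                    shm_step_min = 1, switch_prob_by_v = spv,
                    pb_given_switched = 0, pb_given_unswitched = 0)
  sim <- simulate_repertoire(gs, cfg, seed = 52)
  sp <- switch_probabilities(unique_bcr_table(cells_to_bcr_table(sim, gs)),
                             min_reads = 100)
  g <- sp$gene
  for (i in seq_len(nrow(g))) {
    truth <- spv[[g$gene[i]]]
    ci <- g$p_switched[i] +
      c(-1.96, 1.96) * sqrt(g$p_switched[i] * (1 - g$p_switched[i]) / g$fx[i])
    expect_true(truth >= ci[1] && truth <= ci[2])
  }
})

test_that("CLL partition rules are disjoint, exhaustive and rule-3-aware", {
  # dominant clone AAAA/AAAT (shared CDR3 "CAR"), one same-CDR3 record,
  # one V-J-only record, one unrelated record
  tab <- data.table::data.table(
    sequence_id = sprintf("r%d", 1:5),
    sequence = c("AAAA", "AAAT", "GGGG", "CCCC", "TTTT"),
    c_call = "IGHM",
    duplicate_count = c(40L, 10L, 2L, 2L, 2L),
    v_call = c("V1", "V1", "V9", "V1", "V3"),
    j_call = "J1",
    junction_aa = c("CAR", "CAR", "CAR", "OTHER", "ELSE"),
    n_mut_total = 0L, sample_id = "cll")
  part <- partition_cll(tab)
  expect_setequal(part$malignant, c("r1", "r2", "r3"))  # rules (1) and (2)
  expect_setequal(part$excluded_vj_only, "r4")          # rule (3) only
  expect_setequal(part$non_malignant, "r5")
  expect_length(intersect(part$malignant, part$non_malignant), 0)
  expect_setequal(c(part$malignant, part$non_malignant,
                    part$excluded_vj_only), tab$sequence_id)
  # healthy-style input still yields a well-formed partition, with a warning
  gs <- test_germline()
  sim <- simulate_repertoire(gs, sim_config(n_clones = 150), seed = 53)
  h <- cells_to_bcr_table(sim, gs)
  expect_warning(ph <- partition_cll(h), "dominant")
  expect_setequal(c(ph$malignant, ph$non_malignant, ph$excluded_vj_only),
                  h$sequence_id)
})

test_that("IGHV profiles normalise, correlate and test non-randomness", {
  set.seed(61)
  genes <- sprintf("IGHV%d-g%02d", rep(1:5, 6), 1:30)
  # identical (but non-uniform) usage across isotypes -> all correlations 1
  n_per <- as.integer(round(seq(5, 60, length.out = 30)))
  mk_iso_tab <- function(counts, iso, muts = 1L) {
    mk_tab(sprintf("%s_%s_%d", iso, rep(genes, counts),
                   sequence(counts)),
           iso, v_call = rep(genes, counts), n_mut_total = muts,
           duplicate_count = 10L)
  }
  tab_eq <- rbind(mk_iso_tab(n_per, "IGHM", 0L), mk_iso_tab(n_per, "IGHG1"),
                  mk_iso_tab(n_per, "IGHA1"))
  pr <- ighv_isotype_profiles(unique_bcr_table(tab_eq), min_reads = 100)
  expect_true(all(abs(colSums(pr$freq) - 100) < 1e-9))
  expect_true(all(abs(pr$correlation$estimate - 1) < 1e-12))
  # anti-correlated usage between IgM and IgG1/2 -> negative correlation
  up <- as.integer(round(seq(2, 60, length.out = 30)))
  down <- rev(up)
  tab_anti <- rbind(mk_iso_tab(up, "IGHM", 0L), mk_iso_tab(down, "IGHG1"))
  pr2 <- ighv_isotype_profiles(unique_bcr_table(tab_anti), min_reads = 100)
  expect_lt(pr2$correlation$estimate["IgM", "IgG1/2"], -0.8)
  expect_lt(pr2$correlation$p_value["IgM", "IgG1/2"], 0.05)
  nr <- pr2$nonrandomness[pr2$nonrandomness$class == "IgG1/2"]
  expect_lt(nr$p_contingency, 0.05)
})

test_that("cohort comparisons behave under identity and strong shifts", {
  x <- c(1.2, 1.9, 2.4, 3.1, 0.8, 1.5, 2.0, 2.8, 1.1, 2.2)
  same <- compare_groups(c(x, x), rep(c("a", "b"), each = 10))
  expect_equal(same$p_value, 1, tolerance = 0.05)
  shifted <- compare_groups(c(x, x + 3 * sd(x)),
                            rep(c("a", "b"), each = 10))
  expect_lt(shifted$p_value, 0.005)
  degen <- compare_groups(rep(1, 6), rep(c("a", "b"), each = 3))
  expect_true(degen$flagged)
  expect_error(compare_groups(1:6, rep("a", 6)), "2 groups")
})

test_that("ANOVA models detect gene effects and gene-by-mutation interaction", {
  set.seed(71)
  genes <- sprintf("IGHV%d-x", 1:4)
  base_p <- c(0.15, 0.30, 0.45, 0.60)
  # interaction: gene 1 switches much more when mutated, gene 4 does not
  mut_boost <- c(0.35, 0.2, 0.1, 0.0)
  tabs <- list()
  for (s in 1:8) {
    for (gi in 1:4) {
      n <- 150
      mutated <- rep(c(TRUE, FALSE), length.out = n)
      p <- ifelse(mutated, base_p[gi] + mut_boost[gi], base_p[gi])
      sw <- runif(n) < p
      tabs[[length(tabs) + 1]] <- mk_tab(
        sprintf("s%d_g%d_%03d", s, gi, 1:n),
        ifelse(sw, "IGHG1", "IGHM"), v_call = genes[gi],
        n_mut_total = as.integer(mutated), sample_id = sprintf("s%d", s))
    }
  }
  ut <- unique_bcr_table(data.table::rbindlist(tabs))
  res <- switch_anova(ut, min_reads = 100)
  expect_lt(res$one_way$p_value[res$one_way$term == "gene"], 0.005)
  tw <- res$two_way
  expect_lt(tw$p_value[tw$term == "status"], 0.005)
  expect_lt(tw$p_value[tw$term == "gene:status"], 0.05)
})
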