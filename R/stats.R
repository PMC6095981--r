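#' Collapse an annotated table to unique BCR records
#'
#' A unique BCR is a distinct V(D)J nucleotide sequence within a sample. The
#' returned table holds one row per (sample, sequence, isotype) presence
#' event with summed read support; mutation counts and calls are properties
#' of the sequence and are carried through. All frequency and conditional
#' probability analyses run on unique records to control for differential
#' RNA per cell (plasmablasts carry orders of magnitude more BCR transcripts
#' than naive cells).
#'
#' @param airr `data.table` with `sample_id`, `sequence`, `c_call`,
#'   `duplicate_count` and annotation columns.
#' @return `data.table`, one row per (sample_id, sequence, c_call).
#' @export
unique_bcr_table <- function(airr) {
  dt <- data.table::as.data.table(airr)
  if (!"sample_id" %in% names(dt)) dt[, sample_id := "sample1"]
  carry <- intersect(c("v_call", "j_call", "junction_aa", "n_mut_total",
                       "n_mut_silent", "n_mut_nonsilent"), names(dt))
  dt[, c(list(duplicate_count = sum(duplicate_count)),
         lapply(.SD, data.table::first)),
     by = .(sample_id, sequence, c_call), .SDcols = carry]
}

#' Per-isotype frequencies of unique BCRs
#'
#' For each isotype class, 100 x (number of unique V(D)J sequences observed
#' in that class) / (total isotype-presence events of unique sequences), so
#' percentages sum to 100 within a sample; a sequence observed in k classes
#' contributes to k numerators. `weight = "reads"` instead weights each
#' presence by its read support — the comparison of the two exposes the
#' RNA-per-cell bias that unique-BCR counting removes.
#'
#' @param utab Output of [unique_bcr_table()].
#' @param weight `"unique"` (default) or `"reads"`.
#' @param scheme Isotype grouping passed to [group_isotypes()].
#' @return `data.table` with `sample_id`, `isotype_group`, `n`, `freq`
#'   (percent).
#' @export
isotype_frequencies <- function(utab, weight = c("unique", "reads"),
                                scheme = "overlap") {
  weight <- match.arg(weight)
  dt <- data.table::as.data.table(utab)
  if (nrow(dt) == 0L) stop("empty unique-BCR table")
  dt <- data.table::copy(dt)
  dt[, isotype_group := group_isotypes(c_call, scheme = scheme)]
  # one presence event per (sample, sequence, class)
  pres <- dt[, .(duplicate_count = sum(duplicate_count)),
             by = .(sample_id, sequence, isotype_group)]
  pres$w <- if (weight == "unique") 1 else pres$duplicate_count
  out <- pres[, .(n = .N, weight_sum = sum(w)), by = .(sample_id, isotype_group)]
  out[, freq := 100 * weight_sum / sum(weight_sum), by = sample_id]
  out[, weight_sum := NULL]
  out[]
}

#' Per-sample, per-isotype CDR3 and mutation summaries
#'
#' Mean CDR3 amino-acid length and median silent / non-silent V-region
#' mutation counts per unique BCR, per isotype class and sample.
#'
#' @param utab Output of [unique_bcr_table()].
#' @param scheme Isotype grouping (default `"class"`).
#' @return `data.table` with `sample_id`, `isotype_group`, `n_unique`,
#'   `mean_cdr3_length`, `median_mut_silent`, `median_mut_nonsilent`.
#'   Classes with no records are simply absent.
#' @export
sample_summaries <- function(utab, scheme = "class") {
  dt <- data.table::copy(data.table::as.data.table(utab))
  dt[, isotype_group := group_isotypes(c_call, scheme = scheme)]
  pres <- dt[, .(junction_aa = data.table::first(junction_aa),
                 n_mut_silent = data.table::first(n_mut_silent),
                 n_mut_nonsilent = data.table::first(n_mut_nonsilent)),
             by = .(sample_id, sequence, isotype_group)]
  pres[, .(n_unique = .N,
           mean_cdr3_length = mean(nchar(junction_aa), na.rm = TRUE),
           median_mut_silent = as.numeric(stats::median(n_mut_silent)),
           median_mut_nonsilent = as.numeric(stats::median(n_mut_nonsilent))),
       by = .(sample_id, isotype_group)]
}

#' Separate malignant and non-malignant BCRs of a CLL repertoire
#'
#' Three rules anchored on the largest cluster: (1) BCRs in the largest CLL
#' cluster, (2) BCRs with a CDR3 identical to any CDR3 in (1), and (3) BCRs
#' sharing a V-J gene combination with (1). The leukemic (malignant)
#' repertoire is (1) union (2). The non-malignant repertoire excludes (1),
#' (2) and (3); records matching only rule (3) are quarantined in neither
#' set, since they are excluded from the non-malignant repertoire but do not
#' meet the leukemic definition.
#'
#' @param airr Annotated `data.table` for one sample.
#' @param net Optional pre-built `ClonalNetwork` for the same records.
#' @param cdr3 `"aa"` (default; amino-acid CDR3 identity) or `"nt"`.
#' @return A `RepertoirePartition`: list of `sequence_id` vectors
#'   `malignant`, `non_malignant`, `excluded_vj_only`, plus
#'   `largest_cluster_id` and the dominant read fraction.
#' @export
partition_cll <- function(airr, net = NULL, cdr3 = c("aa", "nt")) {
  cdr3 <- match.arg(cdr3)
  dt <- data.table::as.data.table(airr)
  if (is.null(net)) net <- build_network(dt)
  cid <- largest_cluster(net, by = "reads")
  mem <- net$vertices[net$vertices$cluster_id == cid, ]
  frac <- sum(mem$duplicate_count) / sum(net$vertices$duplicate_count)
  if (frac < 0.5)
    warning(sprintf(
      "largest cluster holds only %.1f%% of reads; CLL-style partition of a",
      100 * frac), " repertoire without a dominant clone")
  r1_seq <- mem$sequence
  in_r1 <- dt$sequence %in% r1_seq
  if (cdr3 == "aa") {
    key <- dt$junction_aa
  } else {
    key <- dt$sequence  # nt-level identity key handled below
  }
  r1_cdr3 <- unique(key[in_r1])
  r1_cdr3 <- r1_cdr3[!is.na(r1_cdr3)]
  in_r2 <- !is.na(key) & key %in% r1_cdr3
  vj <- paste(dt$v_call, dt$j_call)
  r1_vj <- unique(vj[in_r1])
  in_r3 <- vj %in% r1_vj
  malignant <- in_r1 | in_r2
  vj_only <- in_r3 & !malignant
  structure(list(
    malignant = dt$sequence_id[malignant],
    non_malignant = dt$sequence_id[!malignant & !vj_only],
    excluded_vj_only = dt$sequence_id[vj_only],
    largest_cluster_id = cid,
    dominant_read_fraction = frac), class = "RepertoirePartition")
}

#' @export
print.RepertoirePartition <- function(x, ...) {
  cat(sprintf(
    "RepertoirePartition: %d malignant, %d non-malignant, %d excluded (V-J only); dominant cluster %d (%.1f%% of reads)\n",
    length(x$malignant), length(x$non_malignant), length(x$excluded_vj_only),
    x$largest_cluster_id, 100 * x$dominant_read_fraction))
  invisible(x)
}

#' Isotype clonal overlap coefficients
#'
#' The overlap coefficient of isotype classes X and Y is the relative
#' frequency of unique V(D)J sequences observed in exactly those two
#' classes. To control for sequencing depth, `n_sub` subsamples of `depth`
#' reads are drawn without replacement (reads = barcode-corrected molecules,
#' weighted by `duplicate_count`); within each subsample, every unique
#' sequence whose observed class set has size exactly 2 increments its pair,
#' pair counts are normalised to sum to 1, and the coefficients are averaged
#' over subsamples. IgM and IgD are merged into one IgD/M class first.
#'
#' @param utab [unique_bcr_table()] output for one sample.
#' @param depth Reads per subsample (default 8000).
#' @param n_sub Number of subsamples (default 20).
#' @param seed Integer seed for the subsampling.
#' @return An `OverlapMatrix`: list with `mean` and `se` (symmetric class x
#'   class matrices; diagonal zero; upper-triangle entries of `mean` sum to
#'   1 when any event was observed), `n_subsamples`, `depth`, `subsampled`
#'   (`FALSE` when the sample had fewer than `depth` reads and a single full
#'   pass was used), `flagged` (`TRUE` when no 2-class event was observed).
#' @export
overlap_coefficients <- function(utab, depth = 8000L, n_sub = 20L, seed = 1) {
  dt <- data.table::copy(data.table::as.data.table(utab))
  if (length(unique(dt$sample_id)) > 1L)
    stop("overlap_coefficients operates on a single sample")
  dt[, isotype_group := group_isotypes(c_call, scheme = "overlap")]
  pres <- dt[, .(reads = sum(duplicate_count)),
             by = .(sequence, isotype_group)]
  lev <- isotype_class_levels("overlap")
  nlev <- length(lev)
  seq_idx <- match(pres$sequence, unique(pres$sequence))
  cls_idx <- match(pres$isotype_group, lev)
  unit_seq <- rep(seq_idx, pres$reads)
  unit_cls <- rep(cls_idx, pres$reads)
  total <- length(unit_seq)
  subsampled <- total >= depth
  n_draws <- if (subsampled) n_sub else 1L
  mats <- array(0, c(nlev, nlev, n_draws))
  any_event <- FALSE
  with_seed(seed, {
    for (s in seq_len(n_draws)) {
      if (subsampled) {
        take <- sample.int(total, depth)
        ss <- unique(data.table::data.table(seq = unit_seq[take],
                                            cls = unit_cls[take]))
      } else {
        ss <- unique(data.table::data.table(seq = unit_seq, cls = unit_cls))
      }
      nk <- ss[, .(k = .N, c1 = min(cls), c2 = max(cls)), by = seq]
      two <- nk[nk$k == 2L]
      if (nrow(two) == 0L) next
      any_event <- TRUE
      cnt <- two[, .N, by = .(c1, c2)]
      m <- matrix(0, nlev, nlev)
      m[cbind(cnt$c1, cnt$c2)] <- cnt$N
      mats[, , s] <- m / sum(m)
    }
  })
  mean_m <- apply(mats, c(1, 2), mean)
  se_m <- if (n_draws > 1L) apply(mats, c(1, 2), stats::sd) / sqrt(n_draws)
          else matrix(NA_real_, nlev, nlev)
  mean_m <- mean_m + t(mean_m)
  diag(mean_m) <- 0
  se_sym <- se_m + t(se_m); diag(se_sym) <- 0
  dimnames(mean_m) <- dimnames(se_sym) <- list(lev, lev)
  structure(list(mean = mean_m, se = se_sym, n_subsamples = n_draws,
                 depth = depth, subsampled = subsampled,
                 flagged = !any_event),
            class = "OverlapMatrix")
}

#' @export
print.OverlapMatrix <- function(x, ...) {
  cat(sprintf("OverlapMatrix: %d subsamples of %d reads%s\n",
              x$n_subsamples, x$depth,
              if (!x$subsampled) " (sample below depth; single full pass)"
              else ""))
  print(round(x$mean, 4))
  invisible(x)
}

#' Conditional class-switch probabilities given V gene identity
#'
#' All probabilities are ratios of unique-BCR counts. A unique BCR is
#' switched iff it is observed in any isotype other than IgM/IgD, and
#' mutated iff it carries one or more nucleotide mutations in its V region.
#' Genes (or gene families) are retained when their total read support
#' exceeds `min_reads` and they occur in more than `min_samples` samples.
#'
#' @param utab [unique_bcr_table()] output (any number of samples).
#' @param level `"gene"` or `"family"` (family = the name prefix before
#'   `-`).
#' @param min_reads Strict read-support threshold (default 100, the support level at which gene-level ratios stabilise).
#' @param min_samples Strict sample-count threshold (0 disables; set 5 for
#'   cohort-level isotype-destination probabilities).
#' @param by_sample If `TRUE`, compute the gene table per sample (for ANOVA
#'   modelling); the read/sample filters are still applied cohort-wide.
#' @return A `SwitchProbabilityTable`: list with `gene`
#'   (`data.table`: gene, fx, n_samples, reads, p_mutated, p_unmutated,
#'   p_switched, p_switched_mutated, p_switched_unmutated; plus `sample_id`
#'   when `by_sample`), `isotype` (`data.table`: gene, isotype_group,
#'   p_isotype_given_switched, n), and the filter settings.
#' @export
switch_probabilities <- function(utab, level = c("gene", "family"),
                                 min_reads = 100L, min_samples = 0L,
                                 by_sample = FALSE) {
  level <- match.arg(level)
  dt <- data.table::copy(data.table::as.data.table(utab))
  dt[, gene := if (level == "family") sub("-.*$", "", v_call) else v_call]
  # one row per unique BCR (sample x sequence)
  uniq <- dt[, .(gene = data.table::first(gene),
                 switched = any(is_switched(c_call)),
                 mutated = data.table::first(n_mut_total) >= 1L,
                 reads = sum(duplicate_count),
                 iso_set = list(unique(c_call))),
             by = .(sample_id, sequence)]
  support <- uniq[, .(reads = sum(reads),
                      n_samples = length(unique(sample_id))), by = gene]
  keep <- support[support$reads > min_reads & support$n_samples > min_samples]
  uniq <- uniq[uniq$gene %in% keep$gene]
  if (nrow(uniq) == 0L)
    stop("no gene passes the support filters")
  grp <- if (by_sample) c("sample_id", "gene") else "gene"
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  gene_tab <- uniq[, {
    fx <- .N
    n_mut <- sum(mutated); n_sw <- sum(switched)
    list(fx = fx, reads = sum(reads),
         n_samples = length(unique(sample_id)),
         p_mutated = n_mut / fx, p_unmutated = (fx - n_mut) / fx,
         p_switched = n_sw / fx,
         p_switched_mutated = ratio(sum(switched & mutated), n_mut),
         p_switched_unmutated = ratio(sum(switched & !mutated), fx - n_mut))
  }, by = grp]
  # destination isotype table: presence events of switched classes
  sw <- uniq[uniq$switched]
  iso_tab <- if (nrow(sw)) {
    long <- sw[, .(isotype_group = unique(
      group_isotypes(setdiff(unlist(iso_set), c("IGHM", "IGHD")),
                     scheme = "overlap"))), by = .(sample_id, sequence, gene)]
    it <- long[, .(n = .N), by = .(gene, isotype_group)]
    it[, p_isotype_given_switched := n / sum(n), by = gene]
    it[]
  } else {
    data.table::data.table(gene = character(0), isotype_group = character(0),
                           n = integer(0),
                           p_isotype_given_switched = numeric(0))
  }
  structure(list(gene = gene_tab[], isotype = iso_tab, level = level,
                 min_reads = min_reads, min_samples = min_samples,
                 by_sample = by_sample),
            class = "SwitchProbabilityTable")
}

#' @export
print.SwitchProbabilityTable <- function(x, ...) {
  cat(sprintf("SwitchProbabilityTable (%s level, >%d reads, >%d samples)\n",
              x$level, x$min_reads, x$min_samples))
  print(x$gene)
  invisible(x)
}

#' Isotype-specific IGHV gene usage profiles
#'
#' Per isotype class, the frequency (%) of each IGHV gene among that class's
#' unique BCR presences; genes supported by fewer than `min_reads` reads in
#' total are excluded. Pairwise between-class correlations of the gene
#' frequency vectors are computed (Spearman by default), and each switched
#' class is tested for non-random gene usage against the unmutated IgD/M
#' baseline: per gene a 2x2 chi-squared test (gene vs rest x class vs
#' baseline, no continuity correction) with Benjamini-Hochberg correction,
#' plus the full genes x 2 contingency chi-squared as the per-class summary.
#'
#' @param utab [unique_bcr_table()] output.
#' @param min_reads Genes with read support below this are excluded
#'   (default 100).
#' @param method Correlation method, `"spearman"` (default) or `"pearson"`.
#' @param scheme Isotype grouping (default `"class"`, keeping IgM and IgD
#'   separate so their mutual correlation is observable).
#' @return List of class `IghvProfile`: `freq` (gene x class matrix of
#'   percentages, each retained column summing to 100), `counts`,
#'   `correlation` (list of `estimate` and `p_value` matrices),
#'   `nonrandomness` (`data.table`: class, p_contingency, min_q, n_genes),
#'   `genes` (retained gene names).
#' @export
ighv_isotype_profiles <- function(utab, min_reads = 100L,
                                  method = c("spearman", "pearson"),
                                  scheme = "class") {
  method <- match.arg(method)
  dt <- data.table::copy(data.table::as.data.table(utab))
  dt[, isotype_group := group_isotypes(c_call, scheme = scheme)]
  pres <- dt[, .(reads = sum(duplicate_count),
                 unmutated = data.table::first(n_mut_total) == 0L),
             by = .(sample_id, sequence, v_call, isotype_group)]
  support <- pres[, .(reads = sum(reads)), by = v_call]
  genes <- sort(support$v_call[support$reads >= min_reads])
  if (length(genes) == 0L) stop("no IGHV gene passes the read filter")
  pres <- pres[pres$v_call %in% genes]
  classes <- intersect(isotype_class_levels(scheme),
                       unique(pres$isotype_group))
  counts <- matrix(0L, length(genes), length(classes),
                   dimnames = list(genes, classes))
  cnt <- pres[, .N, by = .(v_call, isotype_group)]
  counts[cbind(match(cnt$v_call, genes),
               match(cnt$isotype_group, classes))] <- cnt$N
  freq <- 100 * sweep(counts, 2L, pmax(1L, colSums(counts)), "/")
  est <- pmat <- matrix(NA_real_, length(classes), length(classes),
                        dimnames = list(classes, classes))
  for (a in seq_along(classes)) for (b in seq_along(classes)) {
    if (a == b) { est[a, b] <- 1; pmat[a, b] <- 0; next }
    ct <- suppressWarnings(
      stats::cor.test(freq[, a], freq[, b], method = method, exact = FALSE))
    est[a, b] <- unname(ct$estimate); pmat[a, b] <- ct$p.value
  }
  # baseline: unmutated IgD/M unique presences
  base <- pres[pres$unmutated &
                 pres$isotype_group %in% c("IgM", "IgD", "IgD/M")]
  base_cnt <- setNames(integer(length(genes)), genes)
  if (nrow(base)) {
    bc <- base[, .N, by = v_call]
    base_cnt[bc$v_call] <- bc$N
  }
  nr_classes <- setdiff(classes, c("IgM", "IgD", "IgD/M"))
  nonr <- data.table::rbindlist(lapply(nr_classes, function(cl) {
    cc <- counts[, cl]
    if (sum(cc) == 0L || sum(base_cnt) == 0L)
      return(data.table::data.table(class = cl, p_contingency = NA_real_,
                                    min_q = NA_real_, n_genes = 0L))
    pcont <- suppressWarnings(
      stats::chisq.test(cbind(cc, base_cnt))$p.value)
    pg <- vapply(seq_along(cc), function(g) {
      tab <- matrix(c(cc[g], sum(cc) - cc[g],
                      base_cnt[g], sum(base_cnt) - base_cnt[g]), 2L)
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    }, numeric(1))
    data.table::data.table(class = cl, p_contingency = pcont,
                           min_q = min(stats::p.adjust(pg, "BH"), na.rm = TRUE),
                           n_genes = length(cc))
  }))
  structure(list(freq = freq, counts = counts,
                 correlation = list(estimate = est, p_value = pmat,
                                    method = method),
                 nonrandomness = nonr, genes = genes),
            class = "IghvProfile")
}

#' Wilcoxon rank-sum comparison of a per-sample metric between cohorts
#'
#' @param values Numeric vector of the per-sample metric.
#' @param groups Factor/character vector of cohort labels (exactly 2
#'   levels).
#' @return `data.table` with `statistic`, `p_value`, `n1`, `n2`, `flagged`
#'   (`TRUE` when a group is degenerate: fewer than 2 values or zero
#'   variance overall).
#' @export
compare_groups <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("compare_groups requires exactly 2 groups")
  x <- values[g == levels(g)[1L]]
  y <- values[g == levels(g)[2L]]
  flagged <- length(x) < 2L || length(y) < 2L || stats::sd(values) == 0
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))
  data.table::data.table(statistic = unname(wt$statistic),
                         p_value = wt$p.value,
                         n1 = length(x), n2 = length(y), flagged = flagged)
}

#' ANOVA models of class-switch probability on gene identity and mutation
#'
#' One-way ANOVA of the per-sample P(switched | gene) on gene identity, and
#' two-way ANOVA (with interaction) of the per-sample conditional switch
#' probability on gene x mutational status.
#'
#' @param utab [unique_bcr_table()] output spanning multiple samples.
#' @param level `"gene"` or `"family"`.
#' @param min_reads,min_samples Support filters (see
#'   [switch_probabilities()]).
#' @return List with `one_way` and `two_way` `data.table`s (term, df,
#'   statistic, p_value, n) and the underlying per-sample table.
#' @export
switch_anova <- function(utab, level = "gene", min_reads = 100L,
                         min_samples = 0L) {
  sp <- switch_probabilities(utab, level = level, min_reads = min_reads,
                             min_samples = min_samples, by_sample = TRUE)
  g <- sp$gene
  tidy_aov <- function(fit, n) {
    s <- summary(fit)[[1L]]
    terms <- trimws(rownames(s))
    keep <- terms != "Residuals"
    data.table::data.table(term = terms[keep], df = s$Df[keep],
                           statistic = s$`F value`[keep],
                           p_value = s$`Pr(>F)`[keep], n = n)
  }
  one_way <- if (length(unique(g$gene)) >= 2L) {
    tidy_aov(stats::aov(p_switched ~ gene, data = g), nrow(g))
  } else data.table::data.table()
  long <- data.table::rbindlist(list(
    g[!is.na(g$p_switched_mutated),
      .(sample_id, gene, status = "mutated", p = p_switched_mutated)],
    g[!is.na(g$p_switched_unmutated),
      .(sample_id, gene, status = "unmutated", p = p_switched_unmutated)]))
  two_way <- if (nrow(long) > 4L && length(unique(long$gene)) >= 2L) {
    tidy_aov(stats::aov(p ~ gene * status, data = long), nrow(long))
  } else data.table::data.table()
  list(one_way = one_way, two_way = two_way, per_sample = g)
}
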