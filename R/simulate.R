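#' Default class-switch transition matrix
#'
#' Row-stochastic 9x9 matrix over the locus-ordered constant genes. Class
#' switching is deletional, so mass is only on the diagonal (no switch) and
#' strictly downstream genes. The default favours the common IgM -> IgG1/2
#' and IgM -> IgA1/2 transitions seen in peripheral blood; `identity = TRUE`
#' gives the no-switch matrix.
#'
#' @param p_stay Probability of remaining on the current gene at a switch
#'   opportunity (terminal IGHA2 always stays).
#' @param identity If `TRUE`, return the identity matrix (no switching).
#' @return Numeric matrix with `IGH_ISOTYPES` dimnames.
#' @export
default_switch_matrix <- function(p_stay = 0.3, identity = FALSE) {
  n <- length(IGH_ISOTYPES)
  m <- matrix(0, n, n, dimnames = list(IGH_ISOTYPES, IGH_ISOTYPES))
  if (identity) { diag(m) <- 1; return(m) }
  # relative attractiveness of each downstream target
  w <- c(IGHM = 0, IGHD = 0, IGHG3 = 2, IGHG1 = 3, IGHA1 = 3,
         IGHG2 = 1.5, IGHG4 = 0.5, IGHE = 0.3, IGHA2 = 1.5)
  for (i in seq_len(n)) {
    down <- if (i < n) seq(i + 1L, n) else integer(0)
    wi <- w[down]
    if (length(wi) == 0 || sum(wi) == 0) { m[i, i] <- 1; next }
    m[i, i] <- p_stay
    m[i, down] <- (1 - p_stay) * wi / sum(wi)
  }
  m
}

validate_switch_matrix <- function(m) {
  if (!is.matrix(m) || !identical(dim(m), c(9L, 9L)) ||
      !identical(rownames(m), IGH_ISOTYPES))
    stop("switch_matrix must be 9x9 with IGH_ISOTYPES dimnames")
  if (any(m < 0)) stop("switch_matrix entries must be >= 0")
  if (any(abs(rowSums(m) - 1) > 1e-9))
    stop("switch_matrix rows must sum to 1 (within 1e-9)")
  for (i in seq_len(9L)) if (i > 1 && any(m[i, seq_len(i - 1L)] > 0))
    stop("switch_matrix has upstream transitions; CSR is deletional")
  invisible(TRUE)
}

#' Simulation parameters for a synthetic BCR repertoire
#'
#' Defaults describe a healthy peripheral-blood repertoire: a majority of
#' unexpanded naive cells (IgM/IgD, no SHM), expanded germinal-centre (GC)
#' clones whose sizes follow a geometric law, per-daughter SHM steps, a
#' locus-ordered downstream switch matrix, and a small plasmablast
#' compartment carrying roughly 1,000-fold more BCR transcripts per cell
#' than naive cells.
#'
#' @param n_clones Number of clones (naive singletons plus GC clones).
#' @param clone_size_law `"geometric"` (size = 1 + Geom(`clone_p`), mean
#'   `1/clone_p`) or `"powerlaw"` (Pareto tail, exponent `powerlaw_alpha`).
#' @param clone_p Geometric parameter.
#' @param powerlaw_alpha Power-law exponent (> 1).
#' @param p_naive Probability a clone is a naive singleton rather than an
#'   expanded GC clone.
#' @param naive_isotype_probs Isotype distribution of naive cells (IgM/IgD).
#' @param founder_shm_rate Per-base SHM probability of a GC clone founder
#'   relative to its germline recombination.
#' @param p_shm_step Probability that a GC daughter cell acquires new SHM.
#' @param shm_step_lambda Poisson mean of new mutations per SHM step.
#' @param shm_step_min Minimum mutations added per SHM step.
#' @param p_switch_step Probability that a GC daughter draws a class-switch
#'   opportunity from `switch_matrix`.
#' @param switch_matrix Row-stochastic downstream transition matrix
#'   (see [default_switch_matrix()]).
#' @param pb_given_switched,pb_given_unswitched Probability that a GC cell is
#'   a plasmablast given its switch status (plasmablasts are enriched among
#'   switched cells).
#' @param rna_copies Named vector of BCR transcript molecules per cell by
#'   cell type. The plasmablast default encodes the >1,000-fold RNA excess
#'   over naive B cells.
#' @param max_n_insert Maximum N-nucleotide insertions per D junction
#'   (uniform on 0..max).
#' @param switch_prob_by_v Optional named vector mapping V-gene names to a
#'   per-cell switch probability; when set, GC cell isotypes are drawn
#'   independently (switched with the gene's probability, uniform over
#'   switched genes) instead of through the lineage matrix. Used for
#'   parameter-recovery experiments.
#' @param dominant_clone Optional list describing a planted dominant (CLL-
#'   like) clone: `read_frac` (target fraction of all molecules),
#'   `founder_mut` (founder SHM count), `p_step` (probability a daughter is 1
#'   mutation from its parent; otherwise 0, keeping the clone Hamming-1
#'   connected), `p_switch` (per-daughter switch-opportunity probability).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_clones = 200L,
                       clone_size_law = c("geometric", "powerlaw"),
                       clone_p = 0.1,
                       powerlaw_alpha = 2.5,
                       p_naive = 0.55,
                       naive_isotype_probs = c(IGHM = 0.7, IGHD = 0.3),
                       founder_shm_rate = 0.02,
                       p_shm_step = 0.85,
                       shm_step_lambda = 2,
                       shm_step_min = 0L,
                       p_switch_step = 0.25,
                       switch_matrix = default_switch_matrix(),
                       pb_given_switched = 0.06,
                       pb_given_unswitched = 0.005,
                       rna_copies = c(naive = 1, memory = 4, plasmablast = 1000),
                       max_n_insert = 12L,
                       switch_prob_by_v = NULL,
                       dominant_clone = NULL) {
  cfg <- list(n_clones = as.integer(n_clones),
              clone_size_law = match.arg(clone_size_law),
              clone_p = clone_p, powerlaw_alpha = powerlaw_alpha,
              p_naive = p_naive, naive_isotype_probs = naive_isotype_probs,
              founder_shm_rate = founder_shm_rate, p_shm_step = p_shm_step,
              shm_step_lambda = shm_step_lambda,
              shm_step_min = as.integer(shm_step_min),
              p_switch_step = p_switch_step, switch_matrix = switch_matrix,
              pb_given_switched = pb_given_switched,
              pb_given_unswitched = pb_given_unswitched,
              rna_copies = rna_copies, max_n_insert = as.integer(max_n_insert),
              switch_prob_by_v = switch_prob_by_v,
              dominant_clone = dominant_clone)
  probs <- c(cfg$p_naive, cfg$founder_shm_rate, cfg$p_shm_step,
             cfg$p_switch_step, cfg$pb_given_switched, cfg$pb_given_unswitched)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  validate_switch_matrix(cfg$switch_matrix)
  structure(cfg, class = "sim_config")
}

draw_clone_size <- function(n, cfg) {
  if (cfg$clone_size_law == "geometric") {
    1L + stats::rgeom(n, cfg$clone_p)
  } else {
    pmax(1L, floor(stats::runif(n)^(-1 / (cfg$powerlaw_alpha - 1))))
  }
}

# Build one V(D)J recombination: V + N1 + D + N2 + J, in frame from the V
# start through the J anchor, stop-free. N2 is drawn uniformly from the
# insertion lengths compatible with the reading frame.
recombine_vdj <- function(germline, cfg, max_tries = 200L) {
  for (t in seq_len(max_tries)) {
    vi <- sample.int(nrow(germline$v), 1L)
    di <- sample.int(nrow(germline$d), 1L)
    ji <- sample.int(nrow(germline$j), 1L)
    n1 <- sample.int(cfg$max_n_insert + 1L, 1L) - 1L
    ld <- nchar(germline$d$seq[di])
    pre_anchor <- germline$j$anchor_start[ji] - 1L
    # frame: junction + pre-anchor length must be a codon multiple
    resid <- (-(n1 + ld + pre_anchor)) %% 3L
    ok_n2 <- seq(resid, cfg$max_n_insert, by = 3L)
    n2 <- sample(ok_n2, 1L)
    seq <- paste0(germline$v$seq[vi],
                  if (n1 > 0) random_dna(n1) else "",
                  germline$d$seq[di],
                  if (n2 > 0) random_dna(n2) else "",
                  germline$j$seq[ji])
    if (!has_stop(seq)) {
      return(list(v_i = vi, d_i = di, j_i = ji, n1 = n1, n2 = n2, seq = seq))
    }
  }
  stop("internal error: could not build a stop-free recombination")
}

truth_cdr3 <- function(seqs, v_len, junction_len, pre_anchor) {
  nt <- substr(seqs, v_len + 1L, v_len + junction_len + pre_anchor)
  vapply(nt, translate_nt, character(1), USE.NAMES = FALSE)
}

#' Simulate a clonally structured, isotype-resolved BCR repertoire
#'
#' Generates cells clone by clone with full ground truth. Naive clones are
#' unexpanded single recombinations (IgM/IgD, no SHM). GC clones grow as a
#' lineage: each daughter copies a random earlier member, optionally adds
#' SHM (stop-free substitutions), and optionally draws a class-switch
#' opportunity from the downstream-only transition matrix. Switch events
#' that leave the nucleotide sequence unchanged are the ground truth behind
#' isotype clonal overlap. An optional dominant clone (Hamming-1 connected,
#' CLL-like) can be planted at a target fraction of all molecules.
#'
#' @param germline A `GermlineSet`.
#' @param config A [sim_config()] list.
#' @param seed Integer seed; output is deterministic given seed and config.
#' @return A `SimRepertoire`: list with `cells` (one row per cell: clone,
#'   type, segments, sequence, SHM counts, true CDR3, isotype, `rna_copies`),
#'   `clones` (per-clone germline recombination), `events` (same-sequence and
#'   mutated switch events with from/to isotype), `config`, `seed`.
#' @export
simulate_repertoire <- function(germline, config = sim_config(), seed = 1) {
  stopifnot(inherits(germline, "GermlineSet"))
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  with_seed(seed, {
    n <- config$n_clones
    is_naive <- stats::runif(n) < config$p_naive
    sizes <- draw_clone_size(n, config)
    sizes[is_naive] <- 1L  # naive cells are unexpanded single recombinations
    out_cells <- vector("list", n + 1L)
    out_events <- vector("list", n + 1L)
    out_clones <- vector("list", n + 1L)
    for (cl in seq_len(n)) {
      g <- gen_clone(cl, sizes[cl], is_naive[cl], germline, config)
      out_cells[[cl]] <- g$cells
      out_events[[cl]] <- g$events
      out_clones[[cl]] <- g$clone
    }
    # planted dominant clone sized to a target molecule fraction
    if (!is.null(config$dominant_clone)) {
      dc <- config$dominant_clone
      base_mol <- sum(unlist(lapply(out_cells[seq_len(n)],
                                    function(x) sum(x$rna_copies))))
      target <- dc$read_frac %||% 0.85
      copies <- unname(config$rna_copies["memory"])
      n_cells <- max(2L, ceiling(target / (1 - target) * base_mol / copies))
      g <- gen_dominant_clone(n + 1L, n_cells, germline, config, dc)
      out_cells[[n + 1L]] <- g$cells
      out_events[[n + 1L]] <- g$events
      out_clones[[n + 1L]] <- g$clone
    }
    cells <- data.table::rbindlist(out_cells)
    cells[, cell_id := sprintf("cell%06d", seq_len(nrow(cells)))]
    events <- data.table::rbindlist(out_events)
    clones <- data.table::rbindlist(out_clones)
    structure(list(cells = cells, clones = clones, events = events,
                   config = config, seed = seed),
              class = "SimRepertoire")
  })
}

# one clone's cells/events/clone-row
gen_clone <- function(clone_id, size, naive, germline, config) {
  rec <- recombine_vdj(germline, config)
  v_len <- nchar(germline$v$seq[rec$v_i])
  junction_len <- rec$n1 + nchar(germline$d$seq[rec$d_i]) + rec$n2
  pre_anchor <- germline$j$anchor_start[rec$j_i] - 1L
  clone_row <- data.table::data.table(
    clone_id = clone_id, naive = naive,
    v_name = germline$v$name[rec$v_i], d_name = germline$d$name[rec$d_i],
    j_name = germline$j$name[rec$j_i], n1 = rec$n1, n2 = rec$n2,
    germline_seq = rec$seq)

  if (naive) {
    iso <- sample(names(config$naive_isotype_probs), size, replace = TRUE,
                  prob = config$naive_isotype_probs)
    cells <- data.table::data.table(
      clone_id = clone_id, cell_type = "naive",
      v_name = clone_row$v_name, d_name = clone_row$d_name,
      j_name = clone_row$j_name, isotype = iso,
      sequence = rec$seq, n_shm_total = 0L, n_shm_v = 0L,
      cdr3_aa = truth_cdr3(rec$seq, v_len, junction_len, pre_anchor),
      rna_copies = unname(config$rna_copies["naive"]))
    return(list(cells = cells, events = NULL, clone = clone_row))
  }

  seqs <- character(size); isos <- character(size)
  ev_from <- character(0); ev_to <- character(0); ev_same <- logical(0)
  k0 <- stats::rbinom(1L, nchar(rec$seq), config$founder_shm_rate)
  seqs[1L] <- mutate_stop_safe(rec$seq, k0)
  by_v <- config$switch_prob_by_v
  draw_iso_indep <- function() {
    p <- unname(by_v[clone_row$v_name])
    if (is.na(p)) p <- 0
    if (stats::runif(1) < p) sample(IGH_ISOTYPES[-(1:2)], 1L) else "IGHM"
  }
  isos[1L] <- if (!is.null(by_v)) draw_iso_indep() else "IGHM"
  if (size > 1L) for (i in seq(2L, size)) {
    parent <- sample.int(i - 1L, 1L)
    s <- seqs[parent]
    if (stats::runif(1) < config$p_shm_step) {
      k <- config$shm_step_min + stats::rpois(1L, config$shm_step_lambda)
      if (k > 0) s <- mutate_stop_safe(s, k)
    }
    seqs[i] <- s
    if (!is.null(by_v)) {
      isos[i] <- draw_iso_indep()
    } else {
      iso <- isos[parent]
      if (stats::runif(1) < config$p_switch_step) {
        new <- sample(IGH_ISOTYPES, 1L, prob = config$switch_matrix[iso, ])
        if (new != iso) {
          ev_from <- c(ev_from, iso); ev_to <- c(ev_to, new)
          ev_same <- c(ev_same, s == seqs[parent])
        }
        iso <- new
      }
      isos[i] <- iso
    }
  }
  switched <- is_switched(isos)
  p_pb <- ifelse(switched, config$pb_given_switched, config$pb_given_unswitched)
  ctype <- ifelse(stats::runif(size) < p_pb, "plasmablast", "memory")
  cells <- data.table::data.table(
    clone_id = clone_id, cell_type = ctype,
    v_name = clone_row$v_name, d_name = clone_row$d_name,
    j_name = clone_row$j_name, isotype = isos, sequence = seqs,
    n_shm_total = mismatch_to_ref_cpp(seqs, rec$seq, nchar(rec$seq)),
    n_shm_v = mismatch_to_ref_cpp(seqs, rec$seq, v_len),
    cdr3_aa = truth_cdr3(seqs, v_len, junction_len, pre_anchor),
    rna_copies = unname(config$rna_copies[ctype]))
  events <- if (length(ev_from))
    data.table::data.table(clone_id = clone_id, from_iso = ev_from,
                           to_iso = ev_to, same_sequence = ev_same)
  else NULL
  list(cells = cells, events = events, clone = clone_row)
}

# Planted dominant clone: a shallow recursive tree around the founder
# (parents drawn mostly from the founder) with steps of at most 1 nt, so the
# clone is one connected component of the Hamming-1 network and member
# sequences stay close to the dominant BCR, as in a CLL clone.
gen_dominant_clone <- function(clone_id, n_cells, germline, config, dc) {
  rec <- recombine_vdj(germline, config)
  v_len <- nchar(germline$v$seq[rec$v_i])
  junction_len <- rec$n1 + nchar(germline$d$seq[rec$d_i]) + rec$n2
  pre_anchor <- germline$j$anchor_start[rec$j_i] - 1L
  founder <- mutate_stop_safe(rec$seq, dc$founder_mut %||% 12L)
  p_step <- dc$p_step %||% 0.3
  p_switch <- dc$p_switch %||% 0.02
  seqs <- character(n_cells); isos <- character(n_cells)
  ev_from <- character(0); ev_to <- character(0); ev_same <- logical(0)
  seqs[1L] <- founder; isos[1L] <- "IGHM"
  if (n_cells > 1L) for (i in seq(2L, n_cells)) {
    parent <- if (stats::runif(1) < 0.8) 1L else sample.int(i - 1L, 1L)
    s <- seqs[parent]
    if (stats::runif(1) < p_step) s <- mutate_stop_safe(s, 1L)
    seqs[i] <- s
    iso <- isos[parent]
    if (stats::runif(1) < p_switch) {
      new <- sample(IGH_ISOTYPES, 1L, prob = config$switch_matrix[iso, ])
      if (new != iso) {
        ev_from <- c(ev_from, iso); ev_to <- c(ev_to, new)
        ev_same <- c(ev_same, s == seqs[parent])
      }
      iso <- new
    }
    isos[i] <- iso
  }
  cells <- data.table::data.table(
    clone_id = clone_id, cell_type = "memory",
    v_name = germline$v$name[rec$v_i], d_name = germline$d$name[rec$d_i],
    j_name = germline$j$name[rec$j_i], isotype = isos, sequence = seqs,
    n_shm_total = mismatch_to_ref_cpp(seqs, rec$seq, nchar(rec$seq)),
    n_shm_v = mismatch_to_ref_cpp(seqs, rec$seq, v_len),
    cdr3_aa = truth_cdr3(seqs, v_len, junction_len, pre_anchor),
    rna_copies = unname(config$rna_copies["memory"]))
  events <- if (length(ev_from))
    data.table::data.table(clone_id = clone_id, from_iso = ev_from,
                           to_iso = ev_to, same_sequence = ev_same)
  else NULL
  clone_row <- data.table::data.table(
    clone_id = clone_id, naive = FALSE,
    v_name = cells$v_name[1], d_name = cells$d_name[1],
    j_name = cells$j_name[1], n1 = rec$n1, n2 = rec$n2,
    germline_seq = rec$seq)
  list(cells = cells, events = events, clone = clone_row)
}

#' @export
print.SimRepertoire <- function(x, ...) {
  cat(sprintf(
    "SimRepertoire: %d cells in %d clones (%d molecules), seed %d\n",
    nrow(x$cells), nrow(x$clones), sum(x$cells$rna_copies), x$seed))
  invisible(x)
}

#' Convert simulated cells to a rearrangement table
#'
#' Builds the AIRR-style table the statistics module consumes directly from
#' the simulation ground truth (one row per cell; `duplicate_count` is the
#' cell's molecule count, i.e. the reads it would contribute after barcode
#' correction). Silent/non-silent counts are computed per codon against the
#' clone's germline V.
#'
#' @param sim A `SimRepertoire`.
#' @param germline The `GermlineSet` used to simulate.
#' @param sample_id Sample label for the `sample_id` column.
#' @return `data.table` with AIRR-style columns (`sequence_id`, `sequence`,
#'   `v_call`, `d_call`, `j_call`, `c_call`, `junction_aa`,
#'   `duplicate_count`, `n_mut_total`, `n_mut_silent`, `n_mut_nonsilent`,
#'   `sample_id`).
#' @export
cells_to_bcr_table <- function(sim, germline, sample_id = "sim1") {
  stopifnot(inherits(sim, "SimRepertoire"))
  cells <- sim$cells
  vmap <- setNames(germline$v$seq, germline$v$name)
  sil <- integer(nrow(cells)); nonsil <- integer(nrow(cells))
  idx <- which(cells$n_shm_v > 0L)
  for (i in idx) {
    m <- count_shm(cells$sequence[i], vmap[[cells$v_name[i]]])
    sil[i] <- m[["n_mut_silent"]]; nonsil[i] <- m[["n_mut_nonsilent"]]
  }
  data.table::data.table(
    sequence_id = cells$cell_id, sequence = cells$sequence,
    v_call = cells$v_name, d_call = cells$d_name, j_call = cells$j_name,
    c_call = cells$isotype, junction_aa = cells$cdr3_aa,
    duplicate_count = cells$rna_copies, n_mut_total = cells$n_shm_v,
    n_mut_silent = sil, n_mut_nonsilent = nonsil,
    sample_id = sample_id, clone_id_true = cells$clone_id)
}

make_barcodes <- function(n) {
  gen <- function(k) {
    ns <- matrix(sample(DNA_BASES, 12L * k, replace = TRUE), nrow = k)
    paste0(ns[, 1], ns[, 2], ns[, 3], ns[, 4], "T",
           ns[, 5], ns[, 6], ns[, 7], ns[, 8], "T",
           ns[, 9], ns[, 10], ns[, 11], ns[, 12], "T")
  }
  bc <- gen(n)
  while (anyDuplicated(bc)) {
    dup <- which(duplicated(bc))
    bc[dup] <- gen(length(dup))
  }
  bc
}

# inject i.i.d. substitution errors and build Phred strings consistent with
# the error model: a fixed fraction of bases is "noisy" with a low quality,
# the rest high quality; the mixture marginal equals error_rate.
inject_errors <- function(seqs, error_rate, read_length) {
  n <- length(seqs)
  if (error_rate == 0) {
    return(list(seqs = seqs,
                quals = rep(strrep(rawToChar(as.raw(40L + 33L)), read_length), n)))
  }
  w <- 0.2
  p_hi <- 1e-4
  p_lo <- (error_rate - (1 - w) * p_hi) / w
  if (p_lo <= p_hi || p_lo > 0.75) stop("error_rate out of supported range")
  q_lo <- max(2L, as.integer(round(-10 * log10(p_lo))))
  q_hi <- 40L
  N <- n * read_length
  noisy <- stats::runif(N) < w
  err <- stats::runif(N) < ifelse(noisy, p_lo, p_hi)
  qraw <- as.raw(ifelse(noisy, q_lo, q_hi) + 33L)
  quals <- vapply(seq_len(n), function(i)
    rawToChar(qraw[((i - 1L) * read_length + 1L):(i * read_length)]),
    character(1))
  idx <- which(err)
  if (length(idx)) {
    ri <- (idx - 1L) %/% read_length + 1L
    pos <- (idx - 1L) %% read_length + 1L
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    pick <- sample.int(3L, length(idx), replace = TRUE)
    for (e in seq_along(idx)) {
      old <- substr(seqs[ri[e]], pos[e], pos[e])
      substr(seqs[ri[e]], pos[e], pos[e]) <- alt[[old]][pick[e]]
    }
  }
  list(seqs = seqs, quals = quals)
}

#' Emit barcoded paired-end reads from a simulated repertoire
#'
#' Each cell contributes `rna_copies` cDNA molecules; each molecule receives
#' a unique 15-nt barcode matching `NNNNTNNNNTNNNNT` (fixed T at 1-based
#' positions 5, 10, 15) and is amplified into `1 + Poisson(pcr_duplicates)`
#' read pairs. The amplicon is, 5' to 3': barcode, the V(D)J sequence, the
#' first `const_trim` bases of the cell's constant gene. R1 reads the
#' amplicon from the barcode end, R2 is the reverse complement of the 3'
#' end; mates always share an identical true overlap greater than
#' `min_overlap`. Substitution errors are i.i.d. per base at `error_rate`
#' with Phred strings drawn from a two-quality mixture whose marginal error
#' rate equals `error_rate` (all Q40 when `error_rate = 0`).
#'
#' @param sim A `SimRepertoire`.
#' @param germline The `GermlineSet` used to simulate.
#' @param error_rate Per-base substitution probability, `0 <= e < 0.1`.
#' @param pcr_duplicates Poisson mean of extra read pairs per molecule.
#' @param read_length Read length of both mates.
#' @param const_trim Constant-gene bases appended to the amplicon (and later
#'   trimmed by the consensus builder).
#' @param min_overlap Minimum guaranteed true mate overlap; amplicons
#'   violating `read_length <= length <= 2*read_length - min_overlap - 1`
#'   raise a configuration error.
#' @param seed Integer seed.
#' @param r1_path,r2_path Optional FASTQ(.gz) output paths.
#' @return A `SimReads` list: `r1`, `r2` (character read sequences), `q1`,
#'   `q2` (Phred strings), `ids`, and truth tables `molecules` (molecule_id,
#'   cell_id, barcode) and `reads` (read_id, molecule_id, barcode).
#' @export
emit_reads <- function(sim, germline, error_rate = 0.004, pcr_duplicates = 1,
                       read_length = 210L, const_trim = 60L,
                       min_overlap = 50L, seed = 1,
                       r1_path = NULL, r2_path = NULL) {
  stopifnot(inherits(sim, "SimRepertoire"))
  if (error_rate < 0 || error_rate >= 0.1)
    stop("error_rate must satisfy 0 <= error_rate < 0.1")
  cells <- sim$cells
  cmap <- setNames(germline$c$seq, germline$c$isotype)
  with_seed(seed, {
    mol_cell <- rep(seq_len(nrow(cells)), cells$rna_copies)
    n_mol <- length(mol_cell)
    barcodes <- make_barcodes(n_mol)
    amplicon <- paste0(barcodes, cells$sequence[mol_cell],
                       substr(cmap[cells$isotype[mol_cell]], 1L, const_trim))
    la <- nchar(amplicon)
    if (any(la < read_length) || any(la > 2L * read_length - min_overlap - 1L))
      stop("configuration error: amplicon lengths [", min(la), ", ", max(la),
           "] incompatible with read_length ", read_length,
           " and min_overlap ", min_overlap)
    copies <- 1L + stats::rpois(n_mol, pcr_duplicates)
    read_mol <- rep(seq_len(n_mol), copies)
    copy_no <- sequence(copies)
    ids <- sprintf("M%07d_C%02d", read_mol, copy_no)
    r1 <- substr(amplicon[read_mol], 1L, read_length)
    r2 <- revcomp(substr(amplicon[read_mol], la[read_mol] - read_length + 1L,
                         la[read_mol]))
    e1 <- inject_errors(r1, error_rate, read_length)
    e2 <- inject_errors(r2, error_rate, read_length)
    out <- structure(list(
      r1 = e1$seqs, q1 = e1$quals, r2 = e2$seqs, q2 = e2$quals, ids = ids,
      molecules = data.table::data.table(
        molecule_id = seq_len(n_mol), cell_id = cells$cell_id[mol_cell],
        clone_id = cells$clone_id[mol_cell], barcode = barcodes,
        v_name = cells$v_name[mol_cell], j_name = cells$j_name[mol_cell],
        isotype = cells$isotype[mol_cell], n_shm = cells$n_shm_total[mol_cell],
        sequence = cells$sequence[mol_cell]),
      reads = data.table::data.table(read_id = ids, molecule_id = read_mol,
                                     barcode = barcodes[read_mol]),
      params = list(error_rate = error_rate, pcr_duplicates = pcr_duplicates,
                    read_length = read_length, const_trim = const_trim,
                    min_overlap = min_overlap, seed = seed)),
      class = "SimReads")
    if (!is.null(r1_path)) write_fastq(out$r1, out$q1, ids, r1_path)
    if (!is.null(r2_path)) write_fastq(out$r2, out$q2, ids, r2_path)
    out
  })
}

#' Emit oriented full-length molecule copies (no pairing)
#'
#' Produces the input the barcode-consensus stage contracts on: oriented
#' (V to constant) copies of each molecule, barcode removed, with i.i.d.
#' substitution errors. This bypasses read pairing and merging and is the
#' entry point used to measure consensus error correction at a known injected
#' error rate.
#'
#' @param sim A `SimRepertoire`.
#' @param germline The `GermlineSet` used to simulate.
#' @param error_rate Per-base substitution probability.
#' @param copies_min Minimum copies per molecule.
#' @param copies_lambda Poisson mean of extra copies.
#' @param const_trim Constant-gene bases appended after the V(D)J sequence.
#' @param seed Integer seed.
#' @return List with `reads` (`data.table`: read_id, molecule_id, barcode,
#'   sequence) and `molecules` truth table (including the true V(D)J
#'   sequence).
#' @export
emit_molecule_copies <- function(sim, germline, error_rate = 0.004,
                                 copies_min = 3L, copies_lambda = 1,
                                 const_trim = 60L, seed = 1) {
  stopifnot(inherits(sim, "SimRepertoire"))
  cells <- sim$cells
  cmap <- setNames(germline$c$seq, germline$c$isotype)
  with_seed(seed, {
    mol_cell <- rep(seq_len(nrow(cells)), cells$rna_copies)
    n_mol <- length(mol_cell)
    barcodes <- make_barcodes(n_mol)
    oriented <- paste0(cells$sequence[mol_cell],
                       substr(cmap[cells$isotype[mol_cell]], 1L, const_trim))
    copies <- copies_min + stats::rpois(n_mol, copies_lambda)
    read_mol <- rep(seq_len(n_mol), copies)
    seqs <- oriented[read_mol]
    if (error_rate > 0) {
      # variable lengths: inject per distinct length block
      lens <- nchar(seqs)
      for (L in unique(lens)) {
        sel <- which(lens == L)
        seqs[sel] <- inject_errors(seqs[sel], error_rate, L)$seqs
      }
    }
    list(reads = data.table::data.table(
           read_id = sprintf("M%07d_C%02d", read_mol, sequence(copies)),
           molecule_id = read_mol, barcode = barcodes[read_mol],
           sequence = seqs),
         molecules = data.table::data.table(
           molecule_id = seq_len(n_mol), cell_id = cells$cell_id[mol_cell],
           barcode = barcodes, isotype = cells$isotype[mol_cell],
           sequence = cells$sequence[mol_cell]),
         params = list(error_rate = error_rate, const_trim = const_trim))
  })
}

write_fastq <- function(seqs, quals, ids, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write the per-read ground truth as TSV
#'
#' @param sim_reads A `SimReads` object from [emit_reads()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_truth_tsv <- function(sim_reads, path) {
  tr <- merge(sim_reads$reads,
              sim_reads$molecules[, .(molecule_id, clone_id, v_name, j_name,
                                      isotype, n_shm)],
              by = "molecule_id")
  data.table::setcolorder(tr, c("read_id", "molecule_id", "barcode"))
  data.table::fwrite(tr, path, sep = "\t")
  invisible(path)
}
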