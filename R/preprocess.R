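#' Read a pair of FASTQ files
#'
#' @param r1_path,r2_path Paths to the mate FASTQ(.gz) files.
#' @return List with `r1`, `q1`, `r2`, `q2`, `ids` (character vectors).
#'   Mate ids (first whitespace token) must match pairwise.
#' @export
read_fastq_pair <- function(r1_path, r2_path) {
  rd <- function(p) {
    # metadata-column drop warning from the reader is irrelevant here
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(p))
    list(seq = as.character(x), qual = as.character(Biostrings::quality(x)),
         ids = sub("\\s.*", "", names(x)))
  }
  a <- rd(r1_path); b <- rd(r2_path)
  if (length(a$seq) != length(b$seq) || !identical(a$ids, b$ids))
    stop("mate ids of R1 and R2 do not match")
  list(r1 = unname(a$seq), q1 = unname(a$qual),
       r2 = unname(b$seq), q2 = unname(b$qual), ids = a$ids)
}

#' Filter read pairs on median base quality
#'
#' A pair is retained iff both mates have median Phred score strictly greater
#' than `min_median_phred`. The median of an even-length read is the mean of
#' the two central values.
#'
#' @param pairs List with `r1`, `q1`, `r2`, `q2`, `ids` (see
#'   [read_fastq_pair()]).
#' @param min_median_phred Strict threshold (default 34).
#' @return The filtered pair list; attribute `n_removed` counts discarded
#'   pairs.
#' @export
quality_filter <- function(pairs, min_median_phred = 34) {
  m1 <- vapply(pairs$q1, phred_median, numeric(1), USE.NAMES = FALSE)
  m2 <- vapply(pairs$q2, phred_median, numeric(1), USE.NAMES = FALSE)
  keep <- m1 > min_median_phred & m2 > min_median_phred
  out <- lapply(pairs, function(x) x[keep])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Merge mate pairs requiring an identical overlap
#'
#' The reverse mate is reverse-complemented and aligned to the forward mate;
#' the pair is merged iff the two share an identical (zero-mismatch) overlap
#' strictly longer than `min_overlap` bases, otherwise it is discarded. The
#' merged sequence is the union of the mates. The search assumes the forward
#' mate starts at or before the reverse-complemented mate (amplicons at
#' least one read long), the geometry barcoded amplicon libraries guarantee.
#'
#' @param pairs Filtered pair list.
#' @param min_overlap Strict minimum overlap (default 50: merging requires
#'   more than 50 identical bases).
#' @param seed_len Length of the exact seed used to locate the overlap
#'   offset; must be `<= min_overlap`.
#' @return `data.table` with `read_id` and merged `sequence`; attribute
#'   `n_unmerged` counts discarded pairs.
#' @export
merge_pairs <- function(pairs, min_overlap = 50L, seed_len = 20L) {
  stopifnot(seed_len <= min_overlap)
  n <- length(pairs$r1)
  rc2 <- if (n) revcomp(pairs$r2) else character(0)
  merged <- character(n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    a <- pairs$r1[i]; b <- rc2[i]
    la <- nchar(a)
    seedv <- substr(b, 1L, seed_len)
    hits <- gregexpr(seedv, a, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) next
    for (p in hits) {
      ov <- la - p + 1L
      if (ov <= min_overlap || ov > nchar(b)) next
      if (substr(a, p, la) == substr(b, 1L, ov)) {
        merged[i] <- paste0(substr(a, 1L, p - 1L), b)
        ok[i] <- TRUE
        break
      }
    }
  }
  out <- data.table::data.table(read_id = pairs$ids[ok], sequence = merged[ok])
  attr(out, "n_unmerged") <- sum(!ok)
  out
}

barcode_ok <- function(x) {
  nchar(x) >= 15L &
    substr(x, 5L, 5L) == "T" & substr(x, 10L, 10L) == "T" &
    substr(x, 15L, 15L) == "T"
}

#' Locate the molecular barcode and orient reads V-to-constant
#'
#' The 15-nt barcode (pattern `NNNNTNNNNTNNNNT`) sits at the 5' end of the
#' correctly oriented read. Reads are checked for the conserved T bases at
#' 1-based positions 5, 10 and 15 on the forward strand and, failing that,
#' on the reverse complement; reads with no valid barcode on either strand
#' are rejected.
#'
#' @param merged `data.table` from [merge_pairs()] (`read_id`, `sequence`).
#' @return `data.table` with `read_id`, `barcode`, `sequence` (barcode
#'   removed, oriented V to constant) and `flipped`; attribute `n_rejected`.
#' @export
extract_barcode <- function(merged) {
  seqs <- merged$sequence
  fwd <- barcode_ok(seqs)
  rc <- revcomp(seqs[!fwd])
  rev_ok <- barcode_ok(rc)
  oriented <- seqs
  oriented[!fwd] <- rc
  keep <- fwd
  keep[!fwd] <- rev_ok
  out <- data.table::data.table(
    read_id = merged$read_id[keep],
    barcode = substr(oriented[keep], 1L, 15L),
    sequence = substr(oriented[keep], 16L, nchar(oriented[keep])),
    flipped = !fwd[keep])
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Call the isotype of oriented reads by constant-region k-mer matching
#'
#' The constant-side segment of each read (its last `tail_len` bases) is
#' scored against the first 50 bp of every constant gene: the score is the
#' number of the gene's 41 possible 10-mers (for `k = 10`) found in the
#' read segment. The call is the unique argmax; ties and all-zero scores
#' yield `"ambiguous"`.
#'
#' @param seqs Character vector of oriented sequences.
#' @param germline A `GermlineSet` (its `c` table is used).
#' @param k k-mer length (default 10).
#' @param tail_len Constant-side window inspected at the read 3' end.
#' @param return_scores If `TRUE`, also return the score matrix.
#' @return Character vector of isotype calls (or a list with `call` and
#'   `scores` when `return_scores = TRUE`).
#' @export
assign_isotype <- function(seqs, germline, k = 10L, tail_len = 60L,
                           return_scores = FALSE) {
  cg <- germline$c
  if (any(nchar(cg$seq) < 50L)) stop("constant genes must be >= 50 nt")
  gene_kmers <- lapply(cg$seq, function(s) {
    pre <- substr(s, 1L, 50L)
    substring(pre, 1:(50L - k + 1L), k:50L)
  })
  all_gk <- unlist(gene_kmers)
  gene_of <- rep(seq_len(nrow(cg)), lengths(gene_kmers))
  n <- length(seqs)
  scores <- matrix(0L, n, nrow(cg), dimnames = list(NULL, cg$isotype))
  for (i in seq_len(n)) {
    s <- seqs[i]
    L <- nchar(s)
    tl <- min(tail_len, L)
    tail_seq <- substr(s, L - tl + 1L, L)
    if (tl < k) next
    rk <- substring(tail_seq, 1:(tl - k + 1L), k:tl)
    hit <- all_gk %in% rk
    if (any(hit)) {
      tab <- tabulate(gene_of[hit], nbins = nrow(cg))
      scores[i, ] <- tab
    }
  }
  best <- max.col(scores, ties.method = "first")
  mx <- scores[cbind(seq_len(n), best)]
  n_at_max <- rowSums(scores == mx)
  call <- ifelse(mx == 0L | n_at_max > 1L, "ambiguous", cg$isotype[best])
  if (return_scores) list(call = call, scores = scores) else call
}

#' Build the consensus of one barcode group
#'
#' Reads are assumed trimmed of primer/constant bases. Only reads of the
#' modal length are used (ties resolved towards the shorter length; dropped
#' reads are counted). The consensus takes the per-position majority base
#' (ties towards the lexicographically smallest base); certainty is the mean
#' over positions of the fraction of used reads matching the consensus base.
#' Singleton groups have certainty 1. Groups are retained iff certainty is
#' strictly greater than the threshold.
#'
#' @param seqs Character vector of reads sharing one barcode (length >= 1).
#' @param certainty_threshold Strict retention threshold (default 0.8).
#' @return List: `consensus`, `certainty`, `read_count` (all members),
#'   `n_used`, `n_dropped_length`, `retained`.
#' @export
build_consensus <- function(seqs, certainty_threshold = 0.8) {
  if (length(seqs) == 0L) stop("empty barcode group")
  lens <- nchar(seqs)
  tab <- table(lens)
  modal <- as.integer(names(tab)[tab == max(tab)])
  modal <- min(modal)
  use <- seqs[lens == modal]
  if (length(use) == 1L) {
    cons <- use
    cert <- 1.0
  } else {
    cc <- consensus_cpp(use)
    cons <- cc$consensus
    cert <- cc$certainty
  }
  list(consensus = cons, certainty = cert, read_count = length(seqs),
       n_used = length(use), n_dropped_length = length(seqs) - length(use),
       retained = cert > certainty_threshold)
}

#' Collapse oriented reads to barcode-group consensus sequences
#'
#' Trims the constant-region bases from each read (by amplicon-design
#' coordinates: the last `const_trim` bases), groups reads by barcode, and
#' builds each group's majority consensus (see [build_consensus()]). The
#' group isotype is the modal member-read call; ties give `"ambiguous"`.
#'
#' @param reads `data.table` with `barcode`, `sequence`, and optionally
#'   `isotype` columns (e.g. [extract_barcode()] output plus
#'   [assign_isotype()] calls).
#' @param certainty_threshold Strict retention threshold on group certainty.
#' @param const_trim Number of constant-gene bases to trim from the 3' end.
#' @return List with `groups` (`data.table`: barcode, consensus, certainty,
#'   read_count, n_used, retained, isotype) and `members` (`data.table`:
#'   barcode, trimmed member sequence) for error-rate estimation.
#' @export
consensus_by_barcode <- function(reads, certainty_threshold = 0.8,
                                 const_trim = 60L) {
  dt <- data.table::as.data.table(reads)
  dt[, sequence := substr(sequence, 1L, pmax(0L, nchar(sequence) - const_trim))]
  has_iso <- "isotype" %in% names(dt)
  groups <- dt[, {
    bc <- build_consensus(sequence, certainty_threshold)
    iso <- if (has_iso) {
      calls <- isotype[isotype != "ambiguous"]
      if (length(calls) == 0L) "ambiguous" else {
        t2 <- sort(table(calls), decreasing = TRUE)
        if (length(t2) > 1L && t2[1L] == t2[2L]) "ambiguous" else names(t2)[1L]
      }
    } else NA_character_
    list(consensus = bc$consensus, certainty = bc$certainty,
         read_count = bc$read_count, n_used = bc$n_used,
         retained = bc$retained, isotype = iso)
  }, by = barcode]
  list(groups = groups, members = dt[, c("barcode", "sequence"), with = FALSE])
}

#' Estimate the pre-correction per-base error rate
#'
#' The rate is the total number of mismatches between member reads and their
#' barcode-group consensus, divided by the total number of member bases
#' compared. Only groups with at least two (modal-length) reads contribute;
#' singletons carry no replicate information.
#'
#' @param cons Output of [consensus_by_barcode()].
#' @return List with `rate` (`NA` if no multi-read group exists, with
#'   `flagged = TRUE`), `n_mismatches`, `n_bases`, `n_groups`.
#' @export
estimate_precorrection_error <- function(cons) {
  multi <- cons$groups[cons$groups$n_used >= 2L, ]
  if (nrow(multi) == 0L)
    return(list(rate = NA_real_, n_mismatches = 0L, n_bases = 0L,
                n_groups = 0L, flagged = TRUE))
  members <- data.table::as.data.table(cons$members)
  mm <- 0L; nb <- 0L
  consensus_of <- setNames(multi$consensus, multi$barcode)
  sel <- members[members$barcode %in% multi$barcode]
  for (bcv in unique(sel$barcode)) {
    cseq <- consensus_of[[bcv]]
    L <- nchar(cseq)
    mem <- sel$sequence[sel$barcode == bcv]
    mem <- mem[nchar(mem) == L]  # modal-length members only
    mm <- mm + sum(mismatch_to_ref_cpp(mem, cseq, L))
    nb <- nb + length(mem) * L
  }
  list(rate = mm / nb, n_mismatches = mm, n_bases = nb,
       n_groups = nrow(multi), flagged = FALSE)
}

#' Remove out-of-frame and non-immunoglobulin consensus sequences
#'
#' A consensus is retained iff (a) it aligns to some germline V and some J
#' segment at identity of at least the configured thresholds and (b) the
#' reading frame from the V start is open (no stop codon) through the
#' sequence.
#'
#' @param groups `data.table` with a `sequence` column (V(D)J consensus).
#' @param germline A `GermlineSet`.
#' @param min_v_identity,min_j_identity Identity thresholds for the V prefix
#'   and J suffix alignments.
#' @return The retained subset with `v_call`, `j_call`, `v_identity`,
#'   `j_identity` columns appended; attribute `n_removed`.
#' @export
frame_and_ig_filter <- function(groups, germline, min_v_identity = 0.8,
                                min_j_identity = 0.8) {
  dt <- data.table::as.data.table(groups)
  vj <- assign_vj(dt$sequence, germline)
  open <- !vapply(dt$sequence, has_stop, logical(1), USE.NAMES = FALSE)
  keep <- vj$v_identity >= min_v_identity & vj$j_identity >= min_j_identity &
    open
  out <- cbind(dt[keep], vj[keep, c("v_call", "j_call", "v_identity",
                                    "j_identity"), with = FALSE])
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Run the full read-preprocessing stage
#'
#' Quality filter, mate merging, barcode extraction and orientation, isotype
#' calling, barcode-group consensus, error-rate estimation, and the
#' frame/immunoglobulin filter, with per-stage counts.
#'
#' @param pairs Pair list (see [read_fastq_pair()]) or a `SimReads` object.
#' @param germline A `GermlineSet`.
#' @param min_median_phred,min_overlap,kmer,certainty,const_trim,tail_len,
#'   min_v_identity,min_j_identity Stage thresholds (defaults as in the
#'   individual stage functions).
#' @return List with `consensus` (retained `data.table`: barcode, sequence,
#'   isotype, duplicate_count, v_call, j_call), `error_rate` (list from
#'   [estimate_precorrection_error()]), and `log` (per-stage counts).
#' @export
preprocess_reads <- function(pairs, germline, min_median_phred = 34,
                             min_overlap = 50L, kmer = 10L, certainty = 0.8,
                             const_trim = 60L, tail_len = 60L,
                             min_v_identity = 0.8, min_j_identity = 0.8) {
  if (inherits(pairs, "SimReads"))
    pairs <- list(r1 = pairs$r1, q1 = pairs$q1, r2 = pairs$r2, q2 = pairs$q2,
                  ids = pairs$ids)
  log <- list(n_pairs = length(pairs$r1))
  pf <- quality_filter(pairs, min_median_phred)
  log$n_quality_removed <- attr(pf, "n_removed")
  mg <- merge_pairs(pf, min_overlap)
  log$n_unmerged <- attr(mg, "n_unmerged")
  bc <- extract_barcode(mg)
  log$n_barcode_rejected <- attr(bc, "n_rejected")
  bc[, isotype := assign_isotype(sequence, germline, k = kmer,
                                 tail_len = tail_len)]
  cons <- consensus_by_barcode(bc, certainty_threshold = certainty,
                               const_trim = const_trim)
  log$n_barcode_groups <- nrow(cons$groups)
  err <- estimate_precorrection_error(cons)
  retained <- cons$groups[cons$groups$retained &
                            cons$groups$isotype != "ambiguous", ]
  log$n_low_certainty <- sum(!cons$groups$retained)
  log$n_ambiguous_isotype <- sum(cons$groups$retained &
                                   cons$groups$isotype == "ambiguous")
  out <- data.table::data.table(
    barcode = retained$barcode, sequence = retained$consensus,
    isotype = retained$isotype, duplicate_count = retained$read_count)
  filt <- frame_and_ig_filter(out, germline, min_v_identity, min_j_identity)
  log$n_frame_ig_removed <- attr(filt, "n_removed")
  log$n_consensus_retained <- nrow(filt)
  list(consensus = filt, error_rate = err, log = log)
}
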