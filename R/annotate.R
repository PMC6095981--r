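#' Assign germline V and J segments by ungapped alignment
#'
#' Amplicons are oriented V-to-constant with the constant region already
#' trimmed, so the V segment occupies the read 5' prefix and the J segment
#' the 3' suffix. Each germline V is aligned ungapped at the read start and
#' each J at the read end; the call is the segment with the highest identity,
#' ties broken by fewest mismatches then by name order.
#'
#' @param seqs Character vector of V(D)J nucleotide sequences.
#' @param germline A `GermlineSet`.
#' @return `data.table` with `v_call`, `j_call`, `v_identity`, `j_identity`,
#'   `v_mismatches`, `j_mismatches`.
#' @export
assign_vj <- function(seqs, germline) {
  n <- length(seqs)
  slen <- nchar(seqs)
  score_side <- function(refs, names, suffix) {
    nm <- matrix(NA_integer_, n, length(refs))
    idm <- matrix(NA_real_, n, length(refs))
    for (g in seq_along(refs)) {
      L <- nchar(refs[g])
      cmp <- pmin(L, slen)
      mm <- if (suffix) suffix_mismatch_cpp(seqs, refs[g], L)
            else mismatch_to_ref_cpp(seqs, refs[g], L)
      nm[, g] <- mm
      idm[, g] <- 1 - mm / cmp
    }
    best <- integer(n)
    for (i in seq_len(n)) {
      o <- order(-idm[i, ], nm[i, ], names)
      best[i] <- o[1L]
    }
    list(call = names[best], identity = idm[cbind(seq_len(n), best)],
         mismatches = nm[cbind(seq_len(n), best)])
  }
  v <- score_side(germline$v$seq, germline$v$name, suffix = FALSE)
  j <- score_side(germline$j$seq, germline$j$name, suffix = TRUE)
  data.table::data.table(
    v_call = v$call, j_call = j$call,
    v_identity = v$identity, j_identity = j$identity,
    v_mismatches = v$mismatches, j_mismatches = j$mismatches)
}

#' Count silent and non-silent mutations in the V region
#'
#' Observed and germline V are compared codon by codon over the aligned V
#' region (the read prefix covered by the germline V, anchored to the V
#' reading frame). A mutated nucleotide is non-silent iff its codon — with
#' all of that codon's observed mutations applied — encodes a different
#' amino acid than the germline codon; otherwise it is silent. Every mutated
#' base of a non-synonymously changed codon therefore counts as non-silent.
#'
#' @param seq Observed V(D)J nucleotide sequence.
#' @param germline_v Germline V segment sequence (in frame from position 1).
#' @return Named integer vector: `n_mut_total`, `n_mut_silent`,
#'   `n_mut_nonsilent`.
#' @export
count_shm <- function(seq, germline_v) {
  L <- min(nchar(seq), nchar(germline_v))
  n_cod <- L %/% 3L
  if (n_cod == 0L)
    return(c(n_mut_total = 0L, n_mut_silent = 0L, n_mut_nonsilent = 0L))
  starts <- seq(1L, by = 3L, length.out = n_cod)
  obs <- substring(seq, starts, starts + 2L)
  ref <- substring(germline_v, starts, starts + 2L)
  diff <- which(obs != ref)
  sil <- 0L; nonsil <- 0L; tot <- 0L
  for (i in diff) {
    nmut <- hamming(obs[i], ref[i])
    tot <- tot + nmut
    if (GENETIC_CODE_VEC[[obs[i]]] == GENETIC_CODE_VEC[[ref[i]]]) {
      sil <- sil + nmut
    } else {
      nonsil <- nonsil + nmut
    }
  }
  c(n_mut_total = tot, n_mut_silent = sil, n_mut_nonsilent = nonsil)
}

#' Extract the CDR3 amino-acid sequence
#'
#' The CDR3 is the translated region strictly between the conserved V-region
#' cysteine codon and the conserved J-region tryptophan/phenylalanine codon
#' (the IMGT junction minus its two anchors). The V anchor is located by the
#' germline V coordinates, the J anchor by the called J's position at the
#' read 3' end; both anchor codons must still encode their conserved residue
#' in the read, otherwise the record is flagged (`NA`).
#'
#' @param seq V(D)J nucleotide sequence.
#' @param v_call,j_call Germline segment names from [assign_vj()].
#' @param germline A `GermlineSet`.
#' @return CDR3 amino-acid string (possibly `""` when the anchors abut), or
#'   `NA_character_` when an anchor is missing/mutated or the region is out
#'   of frame.
#' @export
extract_cdr3 <- function(seq, v_call, j_call, germline) {
  vi <- match(v_call, germline$v$name)
  ji <- match(j_call, germline$j$name)
  if (is.na(vi) || is.na(ji)) return(NA_character_)
  cys_start <- germline$v$cys_start[vi]
  lj <- nchar(germline$j$seq[ji])
  anchor_start <- nchar(seq) - lj + germline$j$anchor_start[ji]
  cys_cod <- substr(seq, cys_start, cys_start + 2L)
  anc_cod <- substr(seq, anchor_start, anchor_start + 2L)
  if (!(cys_cod %in% c("TGT", "TGC"))) return(NA_character_)
  if (!(anc_cod %in% c("TGG", "TTT", "TTC"))) return(NA_character_)
  from <- cys_start + 3L
  to <- anchor_start - 1L
  if (to < from) return("")
  nt <- substr(seq, from, to)
  if (nchar(nt) %% 3L != 0L) return(NA_character_)
  translate_nt(nt)
}

#' Annotate consensus BCR sequences
#'
#' Assigns V/J calls, counts silent and non-silent SHM against the called
#' germline V, and extracts the CDR3, producing an AIRR-style rearrangement
#' table. Records whose best V or J identity falls below threshold are
#' dropped (counted in the `n_unannotatable` attribute).
#'
#' @param consensus `data.table` with `sequence`, `isotype`,
#'   `duplicate_count` columns (e.g. from [preprocess_reads()]), and
#'   optionally `barcode`.
#' @param germline A `GermlineSet`.
#' @param sample_id Sample label.
#' @param min_v_identity,min_j_identity Identity thresholds below which a
#'   record is unannotatable.
#' @return `data.table` with columns `sequence_id`, `sequence`, `v_call`,
#'   `d_call` (`NA`; D assignment is not attempted), `j_call`, `c_call`,
#'   `junction_aa` (CDR3, anchors excluded), `cdr3_length`,
#'   `duplicate_count`, `n_mut_total`, `n_mut_silent`, `n_mut_nonsilent`,
#'   `sample_id`.
#' @export
annotate_bcrs <- function(consensus, germline, sample_id = "sample1",
                          min_v_identity = 0.8, min_j_identity = 0.8) {
  dt <- data.table::as.data.table(consensus)
  vj <- assign_vj(dt$sequence, germline)
  keep <- vj$v_identity >= min_v_identity & vj$j_identity >= min_j_identity
  n_drop <- sum(!keep)
  dt <- dt[keep]; vj <- vj[keep]
  vmap <- setNames(germline$v$seq, germline$v$name)
  n <- nrow(dt)
  tot <- integer(n); sil <- integer(n); nonsil <- integer(n)
  cdr3 <- character(n)
  for (i in seq_len(n)) {
    m <- count_shm(dt$sequence[i], vmap[[vj$v_call[i]]])
    tot[i] <- m[["n_mut_total"]]; sil[i] <- m[["n_mut_silent"]]
    nonsil[i] <- m[["n_mut_nonsilent"]]
    cdr3[i] <- extract_cdr3(dt$sequence[i], vj$v_call[i], vj$j_call[i],
                            germline)
  }
  out <- data.table::data.table(
    sequence_id = if ("barcode" %in% names(dt)) dt$barcode
                  else sprintf("seq%06d", seq_len(n)),
    sequence = dt$sequence,
    v_call = vj$v_call, d_call = NA_character_, j_call = vj$j_call,
    c_call = dt$isotype, junction_aa = cdr3,
    cdr3_length = ifelse(is.na(cdr3), NA_integer_, nchar(cdr3)),
    duplicate_count = dt$duplicate_count,
    n_mut_total = tot, n_mut_silent = sil, n_mut_nonsilent = nonsil,
    sample_id = sample_id)
  attr(out, "n_unannotatable") <- n_drop
  out
}

#' Write an AIRR-style rearrangement table to TSV
#'
#' @param airr `data.table` from [annotate_bcrs()] or [cells_to_bcr_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_airr_tsv <- function(airr, path) {
  data.table::fwrite(airr, path, sep = "\t", na = "")
  invisible(path)
}

#' Read an AIRR-style rearrangement table
#'
#' Alternative entry point for externally annotated data: any TSV with at
#' least `sequence`, `v_call`, `j_call`, `c_call`, `junction_aa`,
#' `duplicate_count` columns can feed the network and statistics stages.
#'
#' @param path TSV path.
#' @return `data.table`.
#' @export
read_airr_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = "")
  need <- c("sequence", "v_call", "j_call", "c_call", "duplicate_count")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("missing required columns: ",
                         paste(miss, collapse = ", "))
  dt
}
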