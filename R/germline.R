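#' Generate a synthetic germline reference set
#'
#' Builds a self-consistent synthetic stand-in for an IGH germline database:
#' V segments (in frame, ending in the conserved CDR3-anchor cysteine codon),
#' D segments, J segments carrying the conserved tryptophan anchor, and one
#' constant gene per isotype. Segment sequences are random but constrained so
#' that downstream calling is decidable: V segments are in frame and
#' stop-free up to the Cys anchor, J segments are stop-free in the anchor
#' frame, and the 50-nt constant-gene prefixes used for k-mer isotype calling
#' differ pairwise in at least 5 positions.
#'
#' V gene names encode a gene family (`IGHV1-sim01` belongs to family
#' `IGHV1`); families cycle over IGHV1-IGHV5 as in the human locus's
#' most-used families.
#'
#' @param n_v,n_d,n_j Number of V (>= 2), D (>= 1) and J (>= 1) segments.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param v_codons Range of V-segment lengths in codons (Cys anchor included).
#' @param c_len Length of each synthetic constant gene (>= 50).
#' @return A `GermlineSet`: list of `data.table`s `v` (name, seq, cys_start,
#'   family), `d` (name, seq), `j` (name, seq, anchor_start), `c` (isotype,
#'   seq). Anchor coordinates are 1-based starts of the anchor codon.
#' @examples
#' gs <- make_germline_set(5, 3, 2, seed = 1)
#' gs$v$name
#' @export
make_germline_set <- function(n_v = 10, n_d = 5, n_j = 4, seed = 1,
                              v_codons = c(54L, 58L), c_len = 80L) {
  if (n_v < 2 || n_j < 1 || n_d < 1) stop("need n_v >= 2, n_d >= 1, n_j >= 1")
  if (c_len < 50) stop("constant genes must be >= 50 nt")
  gs <- with_seed(seed, {
    v <- data.table::rbindlist(lapply(seq_len(n_v), function(i) {
      nc <- sample(seq(v_codons[1], v_codons[2]), 1L)
      body <- paste(sample(SENSE_CODONS, nc - 1L, replace = TRUE), collapse = "")
      cys <- sample(c("TGT", "TGC"), 1L)
      fam <- ((i - 1L) %% 5L) + 1L
      data.table::data.table(
        name = sprintf("IGHV%d-sim%02d", fam, i),
        seq = paste0(body, cys),
        cys_start = 3L * (nc - 1L) + 1L,
        family = sprintf("IGHV%d", fam))
    }))
    d <- data.table::data.table(
      name = sprintf("IGHD%d-sim", seq_len(n_d)),
      seq = vapply(seq_len(n_d), function(i) random_dna(sample(10:20, 1L)),
                   character(1)))
    j <- data.table::rbindlist(lapply(seq_len(n_j), function(i) {
      pre <- random_dna(sample(9:15, 1L))
      tail_cod <- paste(sample(SENSE_CODONS, sample(10:12, 1L), replace = TRUE),
                        collapse = "")
      data.table::data.table(
        name = sprintf("IGHJ%d-sim", i),
        seq = paste0(pre, "TGG", tail_cod),
        anchor_start = nchar(pre) + 1L)
    }))
    cgenes <- data.table::data.table(
      isotype = IGH_ISOTYPES,
      seq = vapply(IGH_ISOTYPES, function(x) random_dna(c_len), character(1)))
    # enforce pairwise >= 5 mismatches over the 50-nt calling prefixes
    repeat {
      pre <- substr(cgenes$seq, 1L, 50L)
      bad <- FALSE
      for (a in seq_len(nrow(cgenes) - 1L)) {
        for (b in seq(a + 1L, nrow(cgenes))) {
          if (hamming(pre[a], pre[b]) < 5L) {
            cgenes$seq[b] <- random_dna(c_len)
            bad <- TRUE
          }
        }
      }
      if (!bad) break
    }
    list(v = v, d = d, j = j, c = cgenes)
  })
  structure(gs, class = "GermlineSet")
}

#' Validate a GermlineSet against its invariants
#'
#' Checks alphabet, name uniqueness, V length and frame, anchor codons,
#' constant-gene length and pairwise prefix divergence. Called internally by
#' the generator; exported so externally supplied references can be vetted.
#'
#' @param gs A `GermlineSet`.
#' @return Invisibly `TRUE`; stops with a message on violation.
#' @export
validate_germline_set <- function(gs) {
  stopifnot(inherits(gs, "GermlineSet"))
  allseq <- c(gs$v$seq, gs$d$seq, gs$j$seq, gs$c$seq)
  if (!all(grepl("^[ACGT]+$", allseq))) stop("sequences must be over {A,C,G,T}")
  nm <- c(gs$v$name, gs$d$name, gs$j$name, gs$c$isotype)
  if (anyDuplicated(nm)) stop("segment names must be unique")
  if (any(nchar(gs$v$seq) < 150L)) stop("V segments must be >= 150 nt")
  for (i in seq_len(nrow(gs$v))) {
    cys <- substr(gs$v$seq[i], gs$v$cys_start[i], gs$v$cys_start[i] + 2L)
    if ((gs$v$cys_start[i] - 1L) %% 3L != 0L || !(cys %in% c("TGT", "TGC")))
      stop("V segment out of frame or missing Cys anchor: ", gs$v$name[i])
    if (has_stop(substr(gs$v$seq[i], 1L, gs$v$cys_start[i] + 2L)))
      stop("V segment contains stop codon before Cys anchor: ", gs$v$name[i])
  }
  for (i in seq_len(nrow(gs$j))) {
    anc <- substr(gs$j$seq[i], gs$j$anchor_start[i], gs$j$anchor_start[i] + 2L)
    if (!(anc %in% c("TGG", "TTT", "TTC")))
      stop("J segment missing Trp/Phe anchor: ", gs$j$name[i])
  }
  if (any(nchar(gs$c$seq) < 50L)) stop("constant genes must be >= 50 nt")
  pre <- substr(gs$c$seq, 1L, 50L)
  for (a in seq_len(length(pre) - 1L)) for (b in seq(a + 1L, length(pre)))
    if (hamming(pre[a], pre[b]) < 5L)
      stop("constant-gene 50-nt prefixes too similar: ",
           gs$c$isotype[a], " vs ", gs$c$isotype[b])
  invisible(TRUE)
}

#' @export
print.GermlineSet <- function(x, ...) {
  cat(sprintf("GermlineSet: %d V, %d D, %d J segments, %d constant genes\n",
              nrow(x$v), nrow(x$d), nrow(x$j), nrow(x$c)))
  invisible(x)
}

#' Write a germline set to FASTA files
#'
#' One file per segment class (`v.fasta`, `d.fasta`, `j.fasta`, `c.fasta`).
#' Anchor coordinates are stored as `key=value` tokens in the header so the
#' set round-trips through [read_germline_fasta()].
#'
#' @param gs A `GermlineSet`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the four file paths.
#' @export
write_germline_fasta <- function(gs, dir) {
  stopifnot(inherits(gs, "GermlineSet"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("v.fasta", "d.fasta", "j.fasta", "c.fasta"))
  wr <- function(seqs, names, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- names
    Biostrings::writeXStringSet(x, path, width = 80L)
  }
  wr(gs$v$seq, sprintf("%s cys_start=%d family=%s", gs$v$name, gs$v$cys_start,
                       gs$v$family), paths[1])
  wr(gs$d$seq, gs$d$name, paths[2])
  wr(gs$j$seq, sprintf("%s anchor_start=%d", gs$j$name, gs$j$anchor_start),
     paths[3])
  wr(gs$c$seq, gs$c$isotype, paths[4])
  invisible(paths)
}

#' Read a germline set from FASTA files written by [write_germline_fasta()]
#'
#' @param dir Directory containing `v.fasta`, `d.fasta`, `j.fasta`, `c.fasta`.
#' @return A validated `GermlineSet`.
#' @export
read_germline_fasta <- function(dir) {
  rd <- function(file) {
    x <- Biostrings::readDNAStringSet(file.path(dir, file))
    data.table::data.table(header = names(x), seq = as.character(x))
  }
  tok <- function(header, key) {
    m <- regmatches(header, regexpr(paste0(key, "=[^ ]+"), header))
    sub(paste0(key, "="), "", m)
  }
  v <- rd("v.fasta")
  j <- rd("j.fasta")
  gs <- list(
    v = data.table::data.table(
      name = sub(" .*", "", v$header), seq = v$seq,
      cys_start = as.integer(tok(v$header, "cys_start")),
      family = tok(v$header, "family")),
    d = {
      d <- rd("d.fasta")
      data.table::data.table(name = sub(" .*", "", d$header), seq = d$seq)
    },
    j = data.table::data.table(
      name = sub(" .*", "", j$header), seq = j$seq,
      anchor_start = as.integer(tok(j$header, "anchor_start"))),
    c = {
      cg <- rd("c.fasta")
      data.table::data.table(isotype = sub(" .*", "", cg$header), seq = cg$seq)
    })
  gs <- structure(gs, class = "GermlineSet")
  validate_germline_set(gs)
  gs
}
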