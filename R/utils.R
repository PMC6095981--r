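# Internal helpers shared across modules.

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  if (length(ra) != length(rb)) stop("hamming() requires equal lengths")
  sum(ra != rb)
}

# Translate a nucleotide string in frame 1; incomplete trailing codon is
# dropped. Stops are "*".
translate_nt <- function(x) {
  n <- 3L * (nchar(x) %/% 3L)
  if (n == 0L) return("")
  codons <- substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
  paste(GENETIC_CODE_VEC[codons], collapse = "")
}

# named codon -> single-letter AA lookup (from Biostrings' standard code)
GENETIC_CODE_VEC <- local({
  gc <- Biostrings::GENETIC_CODE
  v <- as.character(gc)
  names(v) <- names(gc)
  v
})

STOP_CODONS <- names(GENETIC_CODE_VEC)[GENETIC_CODE_VEC == "*"]
SENSE_CODONS <- setdiff(names(GENETIC_CODE_VEC), STOP_CODONS)

has_stop <- function(x) {
  n <- 3L * (nchar(x) %/% 3L)
  if (n == 0L) return(FALSE)
  any(substring(x, seq(1L, n, 3L), seq(3L, n, 3L)) %in% STOP_CODONS)
}

# Substitute `k` random positions of `seq` with a different base, resampling
# any proposal that introduces an in-frame stop codon (frame anchored at
# position 1). Mimics a productive-repertoire constraint: cells whose BCR
# acquires a nonsense mutation are lost.
mutate_stop_safe <- function(seq, k, max_tries = 200L) {
  if (k <= 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  placed <- 0L
  tries <- 0L
  while (placed < k && tries < max_tries * k) {
    tries <- tries + 1L
    pos <- sample.int(L, 1L)
    new <- sample(setdiff(DNA_BASES, chars[pos]), 1L)
    cod_i <- (pos - 1L) %/% 3L           # 0-based codon index
    cod_start <- cod_i * 3L + 1L
    if (cod_start + 2L <= L) {
      cod <- chars[cod_start:(cod_start + 2L)]
      cod[pos - cod_start + 1L] <- new
      if (paste(cod, collapse = "") %in% STOP_CODONS) next
    }
    chars[pos] <- new
    placed <- placed + 1L
  }
  paste(chars, collapse = "")
}

# strict-threshold median of integer Phred scores encoded as an ASCII string
phred_median <- function(qual_string) {
  stats::median(utf8ToInt(qual_string) - 33L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
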